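storage_fixture <- function(root = withr::local_tempdir(.local_envir = parent.frame())) {
  reg <- load_registry(list(schema_version = 1,
    backends = list(
      list(id = "localfiles", kind = "storage", scheme = "file",
           endpoint = ""),
      list(id = "memdata", kind = "storage", scheme = "mem",
           endpoint = "data")),
    tools = list(), users = list()))
  list(sm = storage_manager(reg), root = root)
}

test_that("listing, mkdir and delete behave on both bundled backends", {
  fx <- storage_fixture()
  for (base in c(paste0("file://", fx$root), "mem://data")) {
    d <- paste0(base, "/box")
    st_mkdir(fx$sm, d)
    expect_equal(nrow(st_list(fx$sm, d)), 0L)

    st_write(fx$sm, paste0(d, "/b.txt"), charToRaw("bee"))
    st_write(fx$sm, paste0(d, "/a.txt"), charToRaw("ay"))
    ls1 <- st_list(fx$sm, d)
    expect_equal(ls1$name, c("a.txt", "b.txt"))   # sorted by name
    expect_equal(ls1$kind, c("file", "file"))
    expect_equal(ls1$size, c(2, 3))

    # nested mkdir creates parents
    st_mkdir(fx$sm, paste0(d, "/x/y/z"))
    expect_equal(st_exists(fx$sm, paste0(d, "/x/y/z")), "dir")

    # delete of a non-empty dir needs recursive
    expect_error(st_delete(fx$sm, paste0(d, "/x")), class = "fb_storage_error")
    st_delete(fx$sm, paste0(d, "/x"), recursive = TRUE)
    expect_true(is.na(st_exists(fx$sm, paste0(d, "/x"))))

    # create-then-delete round trip restores the listing
    before <- st_list(fx$sm, d)$name
    st_write(fx$sm, paste0(d, "/tmp.bin"), as.raw(1:4))
    st_delete(fx$sm, paste0(d, "/tmp.bin"))
    expect_equal(st_list(fx$sm, d)$name, before)

    expect_error(st_list(fx$sm, paste0(d, "/ghost")),
                 class = "fb_notfound_error")
    expect_error(st_delete(fx$sm, paste0(d, "/ghost")),
                 class = "fb_notfound_error")
    expect_error(st_mkdir(fx$sm, paste0(d, "/a.txt")),
                 class = "fb_storage_error")
  }
})

test_that("copy preserves bytes across every backend pair", {
  fx <- storage_fixture()
  set.seed(5)
  bases <- c(paste0("file://", fx$root, "/l"), "mem://data/m")
  for (src_base in bases) for (dst_base in bases) {
    for (n in c(0L, 1L, 65536L)) {
      payload <- as.raw(sample(0:255, n, replace = TRUE))
      src <- paste0(src_base, "/in-", n, ".bin")
      dst <- paste0(dst_base, "/out-", basename(src_base), n, ".bin")
      st_write(fx$sm, src, payload)
      rep <- st_copy(fx$sm, src, dst)
      expect_equal(rep$bytes, n)
      expect_identical(st_read(fx$sm, dst), payload)
      expect_equal(rep$sha256, st_digest(fx$sm, src))
    }
  }
})

test_that("zero-byte copies carry the checksum of empty input", {
  fx <- storage_fixture()
  st_write(fx$sm, "mem://data/empty", raw(0))
  rep <- st_copy(fx$sm, "mem://data/empty", "mem://data/empty2")
  expect_equal(rep$bytes, 0)
  expect_equal(rep$sha256, flowbench:::sha256_hex(raw(0)))
})

test_that("copy onto the same path is rejected", {
  fx <- storage_fixture()
  st_write(fx$sm, "mem://data/x", as.raw(1:3))
  expect_error(st_copy(fx$sm, "mem://data/x", "mem://data/x"),
               class = "fb_storage_error")
})

test_that("streaming stays under the buffer ceiling and never spools", {
  fx <- storage_fixture()
  set.seed(17)
  n <- 5 * 2^20
  payload <- as.raw(sample(0:255, n, replace = TRUE))
  st_write(fx$sm, "mem://data/big.bin", payload)
  src_be <- storage_instrumented(storage_resolve(fx$sm, "mem://data/"))

  # watch the local filesystem: the copy must create nothing outside dst
  watch <- file.path(fx$root, "watch")
  dir.create(watch)
  before <- list.files(watch, recursive = TRUE, all.files = TRUE)
  withr::local_dir(watch)

  rep <- st_copy(fx$sm, "mem://data/big.bin", "mem://data/big2.bin",
                 chunk_size = 2^19)
  expect_equal(rep$peak_buffer_bytes, 2^19)
  expect_lte(rep$peak_buffer_bytes, 8 * 2^20)
  expect_gte(rep$chunks, 10L)
  expect_identical(st_digest(fx$sm, "mem://data/big2.bin"), rep$sha256)
  expect_equal(list.files(watch, recursive = TRUE, all.files = TRUE), before)
  expect_equal(src_be$stats$max_chunk, 2^19)

  # an oversized request is clamped to the ceiling
  rep2 <- st_copy(fx$sm, "mem://data/big.bin", "mem://data/big3.bin",
                  chunk_size = 64 * 2^20)
  expect_lte(rep2$peak_buffer_bytes, 8 * 2^20)
})

test_that("rename is copy-then-delete", {
  fx <- storage_fixture()
  st_write(fx$sm, "mem://data/old.txt", charToRaw("hi"))
  st_rename(fx$sm, "mem://data/old.txt", "mem://data/new.txt")
  expect_true(is.na(st_exists(fx$sm, "mem://data/old.txt")))
  expect_equal(rawToChar(st_read(fx$sm, "mem://data/new.txt")), "hi")
})

test_that("operations dispatch purely on scheme: a new mock scheme plugs in", {
  calls <- new.env(parent = emptyenv()); calls$n <- 0L
  register_storage_scheme("mock", function(descriptor) {
    be <- storage_mem(descriptor)  # borrow mem semantics
    old <- be$list
    be$list <- function(path) { calls$n <- calls$n + 1L; old(path) }
    be
  })
  withr::defer({
    pl <- flowbench:::.fb_plugins
    pl$storage <- pl$storage[names(pl$storage) != "mock"]
  })
  reg <- load_registry(list(schema_version = 1,
    backends = list(list(id = "mk", kind = "storage", scheme = "mock",
                         endpoint = "mk")),
    tools = list(), users = list()))
  sm <- storage_manager(reg)
  st_mkdir(sm, "mock://mk/d")
  st_list(sm, "mock://mk/d")
  expect_equal(calls$n, 1L)
})

test_that("credential-gated and unreachable backends block instead of failing", {
  reg <- load_registry(list(schema_version = 1,
    backends = list(
      list(id = "vaulted", kind = "storage", scheme = "mem",
           endpoint = "vaulted", requires_credential = TRUE),
      list(id = "down", kind = "storage", scheme = "mem",
           endpoint = "down", reachable = FALSE)),
    tools = list(), users = list()))
  sm <- storage_manager(reg)
  v <- credential_vault()

  expect_error(st_list(sm, "mem://vaulted/", vault = v, as_user = "alice"),
               class = "fb_blocked")
  vault_store(v, "alice", "vaulted", "token", "pw")
  expect_error(st_list(sm, "mem://vaulted/", vault = v, as_user = "alice"),
               class = "fb_blocked")   # stored but not unlocked
  vault_unlock(v, "alice", "pw")
  expect_equal(nrow(st_list(sm, "mem://vaulted/", vault = v,
                            as_user = "alice")), 0L)

  err <- tryCatch(st_list(sm, "mem://down/"), condition = function(e) e)
  expect_true(is_blocked(err))
  expect_match(conditionMessage(err), "unreachable")
})

test_that("unknown schemes are a configuration error", {
  fx <- storage_fixture()
  expect_error(st_list(fx$sm, "gopher://x/"), class = "fb_config_error")
})
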