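#' Encrypted credential vault
#'
#' Per-(user, backend) secrets are stored encrypted with AES-256-CBC under a
#' key derived from the user's password (bcrypt PBKDF, per-record random
#' salt), with an encrypt-then-MAC HMAC-SHA256 tag so any tampering or a
#' wrong password is an authentication failure, never silent corruption.
#' Plaintext secrets exist only in a RAM cache populated by
#' [vault_unlock()]; they are never written to the store, and the persistence
#' layer never serialises the cache. Asking for a credential that is not
#' unlocked raises a *blocking* condition — the engine parks the dependent
#' task in status `"blocked"` so it can resume once the user logs in.
#'
#' @param con Optional DBI connection to the engine store; if `NULL` the
#'   records live in memory (useful for tests).
#' @return `credential_vault()` returns an object of class `fb_vault`.
#' @examples
#' v <- credential_vault()
#' vault_store(v, "alice", "hpc", "s3cret", password = "pw")
#' vault_unlock(v, "alice", "pw")
#' rawToChar(vault_get(v, "alice", "hpc"))
#' @export
credential_vault <- function(con = NULL) {
  v <- new.env(parent = emptyenv())
  v$con <- con
  v$mem <- new.env(parent = emptyenv())   # records when con is NULL
  v$cache <- new.env(parent = emptyenv()) # (user|backend) -> raw secret
  v$now <- function() as.numeric(Sys.time())
  if (!is.null(con)) ensure_cred_table(con)
  class(v) <- "fb_vault"
  v
}

ensure_cred_table <- function(con) {
  DBI::dbExecute(con, "CREATE TABLE IF NOT EXISTS credentials (
    user TEXT NOT NULL, backend_id TEXT NOT NULL,
    salt TEXT, rounds INTEGER, iv TEXT, ct TEXT, mac TEXT,
    expires_at REAL, created_at REAL,
    PRIMARY KEY (user, backend_id))")
}

cred_key <- function(user, backend_id) paste0(user, "\r", backend_id)

derive_keys <- function(password, salt, rounds) {
  km <- openssl::bcrypt_pbkdf(password, salt, rounds = rounds, size = 64L)
  list(enc = km[1:32], mac = km[33:64])
}

encrypt_secret <- function(secret, password, rounds = 8L) {
  if (is.character(secret)) secret <- charToRaw(secret)
  salt <- openssl::rand_bytes(16)
  iv <- openssl::rand_bytes(16)
  k <- derive_keys(password, salt, rounds)
  ct <- openssl::aes_cbc_encrypt(secret, key = k$enc, iv = iv)
  mac <- openssl::sha256(c(salt, iv, ct), key = k$mac)
  list(salt = bin2hex(salt), rounds = as.integer(rounds), iv = bin2hex(iv),
       ct = bin2hex(ct), mac = bin2hex(mac))
}

decrypt_secret <- function(rec, password) {
  salt <- hex2bin(rec$salt); iv <- hex2bin(rec$iv)
  ct <- hex2bin(rec$ct)
  k <- derive_keys(password, salt, rec$rounds)
  mac <- openssl::sha256(c(salt, iv, ct), key = k$mac)
  if (!identical(bin2hex(mac), rec$mac))
    stop_auth("credential authentication failed (wrong password or tampered record)")
  openssl::aes_cbc_decrypt(ct, key = k$enc, iv = iv)
}

bin2hex <- function(x) paste(sprintf("%02x", as.integer(x)), collapse = "")
hex2bin <- function(x) as.raw(strtoi(substring(x, seq(1, nchar(x), 2),
                                               seq(2, nchar(x), 2)), 16L))

cred_records <- function(v, user = NULL, backend_id = NULL,
                         include_expired = FALSE) {
  if (is.null(v$con)) {
    recs <- mget(ls(v$mem), envir = v$mem)
    df <- do.call(rbind, lapply(recs, function(r)
      data.frame(r[c("user", "backend_id", "salt", "rounds", "iv", "ct",
                     "mac", "expires_at", "created_at")],
                 stringsAsFactors = FALSE)))
    if (is.null(df)) df <- data.frame(user = character(0),
      backend_id = character(0), salt = character(0), rounds = integer(0),
      iv = character(0), ct = character(0), mac = character(0),
      expires_at = numeric(0), created_at = numeric(0),
      stringsAsFactors = FALSE)
  } else {
    df <- DBI::dbGetQuery(v$con, "SELECT * FROM credentials")
  }
  if (!is.null(user)) df <- df[df$user == user, , drop = FALSE]
  if (!is.null(backend_id)) df <- df[df$backend_id == backend_id, , drop = FALSE]
  if (!include_expired)
    df <- df[is.na(df$expires_at) | df$expires_at > v$now(), , drop = FALSE]
  df
}

#' Store an encrypted credential
#'
#' @param v A vault from [credential_vault()].
#' @param user,backend_id The key under which the secret is filed.
#' @param secret The secret (string or raw vector).
#' @param password Password from which the encryption key is derived; must be
#'   non-empty.
#' @param rounds bcrypt PBKDF cost parameter (stored with the record).
#' @param ttl Optional lifetime in seconds; an expired record behaves as if
#'   it were never stored.
#' @return Invisibly, the stored record (ciphertext fields only).
#' @export
vault_store <- function(v, user, backend_id, secret, password, rounds = 8L,
                        ttl = NULL) {
  if (!is.character(password) || length(password) != 1L || !nzchar(password))
    stop_validation("vault password must be a non-empty string")
  enc <- encrypt_secret(secret, password, rounds)
  rec <- c(list(user = user, backend_id = backend_id), enc,
           list(expires_at = if (is.null(ttl)) NA_real_ else v$now() + ttl,
                created_at = v$now()))
  if (is.null(v$con)) {
    v$mem[[cred_key(user, backend_id)]] <- rec
  } else {
    DBI::dbExecute(v$con,
      "INSERT OR REPLACE INTO credentials
       (user, backend_id, salt, rounds, iv, ct, mac, expires_at, created_at)
       VALUES (?,?,?,?,?,?,?,?,?)",
      params = list(user, backend_id, rec$salt, rec$rounds, rec$iv, rec$ct,
                    rec$mac, rec$expires_at, rec$created_at))
  }
  invisible(rec)
}

#' Unlock a user's credentials into the RAM cache
#'
#' Decrypts every stored, unexpired credential of `user` with the given
#' password and caches the plaintexts in memory. A wrong password leaves
#' nothing cached and raises an authentication error.
#'
#' @inheritParams vault_store
#' @return The number of credentials cached.
#' @export
vault_unlock <- function(v, user, password) {
  df <- cred_records(v, user = user)
  if (nrow(df) == 0L) return(0L)
  plains <- list()
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, ])
    plains[[cred_key(user, rec$backend_id)]] <- decrypt_secret(rec, password)
  }
  for (k in names(plains)) v$cache[[k]] <- plains[[k]]
  length(plains)
}

#' Fetch a decrypted credential (or block)
#'
#' Returns the cached plaintext secret, or — when the credential is absent or
#' not yet unlocked — raises the blocking condition that moves dependent
#' tasks to status `"blocked"` (never `"error"`).
#'
#' @inheritParams vault_store
#' @return The secret as a raw vector.
#' @export
vault_get <- function(v, user, backend_id) {
  sec <- v$cache[[cred_key(user, backend_id)]]
  if (is.null(sec))
    signal_blocked(sprintf(
      "credential for (%s, %s) not available in decrypted form",
      user, backend_id), backend_id = backend_id, user = user)
  sec
}

#' @rdname vault_get
#' @param stored_ok Count a stored-but-locked record as present.
#' @return `vault_has()`: logical.
#' @export
vault_has <- function(v, user, backend_id, stored_ok = FALSE) {
  if (!is.null(v$cache[[cred_key(user, backend_id)]])) return(TRUE)
  stored_ok && nrow(cred_records(v, user, backend_id)) > 0L
}

#' Clear the RAM cache (logout / shutdown)
#' @param v A vault.
#' @return Invisibly, the vault.
#' @export
vault_lock <- function(v) {
  rm(list = ls(v$cache), envir = v$cache)
  invisible(v)
}

#' List stored credentials (metadata only)
#' @param v A vault.
#' @param user Optional filter.
#' @return Data frame of `user`, `backend_id`, `expires_at`, `created_at`,
#'   `unlocked`.
#' @export
vault_list <- function(v, user = NULL) {
  df <- cred_records(v, user = user)
  df$unlocked <- vapply(seq_len(nrow(df)), function(i)
    !is.null(v$cache[[cred_key(df$user[i], df$backend_id[i])]]), logical(1))
  df[c("user", "backend_id", "expires_at", "created_at", "unlocked")]
}

#' Remove a stored credential
#' @inheritParams vault_store
#' @return Invisibly, the vault.
#' @export
vault_remove <- function(v, user, backend_id) {
  if (is.null(v$con)) {
    k <- cred_key(user, backend_id)
    if (!is.null(v$mem[[k]])) rm(list = k, envir = v$mem)
  } else {
    DBI::dbExecute(v$con,
      "DELETE FROM credentials WHERE user = ? AND backend_id = ?",
      params = list(user, backend_id))
  }
  k <- cred_key(user, backend_id)
  if (!is.null(v$cache[[k]])) rm(list = k, envir = v$cache)
  invisible(v)
}

#' @export
print.fb_vault <- function(x, ...) {
  df <- cred_records(x)
  cat(sprintf("<vault> %d stored credential(s), %d unlocked\n",
              nrow(df), length(ls(x$cache))))
  invisible(x)
}
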