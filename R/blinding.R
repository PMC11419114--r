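# Keyed, format-preserving blinding codec for trial identifiers.
#
# Observers must score trials blind to subject, group and session, so each
# (rat, session, trial) triple is encoded as an opaque token: a wordlist
# word (chosen by keyed hash) followed by fixed-width digits carrying a
# keyed permutation of the identifier index plus a keyed check code. The
# scheme is reproducible from the key and injective over the identifier
# space; it makes no claim to cryptographic strength - its job is unbiased
# scoring, not secrecy against a determined attacker.

# Multiplicative string hash on a Mersenne-prime modulus; all arithmetic
# stays below 2^53 so doubles are exact.
.eth_hash <- function(..., modulus = 2147483647) {
  bytes <- utf8ToInt(paste(c(...), collapse = "\x1f"))
  h <- 2166136261 %% modulus
  for (b in bytes) h <- (h * 48271 + b + 1) %% modulus
  h
}

# Evaluate expr under a temporary RNG seed, leaving the caller's RNG
# stream untouched.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.blind_wordlist <- function() {
  path <- system.file("extdata", "wordlist.txt", package = "ethofear")
  if (path == "") path <- file.path("inst", "extdata", "wordlist.txt")
  readLines(path)
}

.blind_space <- function(ranges) {
  stopifnot(all(ranges >= 1))
  prod(ranges)
}

.blind_index <- function(rat, session, trial, ranges) {
  if (rat < 1 || rat > ranges[1] || session < 1 || session > ranges[2] ||
      trial < 1 || trial > ranges[3]) {
    stop("identifier out of configured range", call. = FALSE)
  }
  ((rat - 1) * ranges[2] + (session - 1)) * ranges[3] + (trial - 1)
}

.blind_perm <- function(key, n) {
  .with_seed(.eth_hash("perm", key) %% 2147483646 + 1, sample.int(n))
}

#' Encode trial identifiers as a blinded token
#'
#' Produces an opaque word+digits token (e.g. `"maple00312407"`) from which
#' rat, session and trial numbers can be recovered only with the key.
#' Tokens for distinct identifiers are distinct, and consecutive trials get
#' unrelated tokens.
#'
#' @param rat_id,session_id,trial_index Positive integers within `ranges`.
#' @param key Non-empty secret string.
#' @param ranges Integer vector `c(max_rat, max_session, max_trial)`
#'   defining the identifier space (defaults fit 64 rats, 16 sessions,
#'   8 trials).
#' @return Character token: lowercase word followed by 8 digits.
#' @export
encode_trial <- function(rat_id, session_id, trial_index, key,
                         ranges = c(64L, 16L, 8L)) {
  if (!is.character(key) || length(key) != 1 || nchar(key) == 0) {
    stop("key must be a non-empty string", call. = FALSE)
  }
  n <- .blind_space(ranges)
  idx <- .blind_index(rat_id, session_id, trial_index, ranges)
  perm <- .blind_perm(key, n)
  code <- perm[idx + 1] - 1
  mac <- .eth_hash("mac", key, idx) %% 1000
  words <- .blind_wordlist()
  word <- words[.eth_hash("word", key, idx) %% length(words) + 1]
  sprintf("%s%05d%03d", word, code, mac)
}

#' Decode a blinded trial token
#'
#' @param token Token produced by [encode_trial()].
#' @inheritParams encode_trial
#' @return Named list with `rat_id`, `session_id`, `trial_index`.
#' @export
decode_trial <- function(token, key, ranges = c(64L, 16L, 8L)) {
  if (!is.character(key) || length(key) != 1 || nchar(key) == 0) {
    stop("key must be a non-empty string", call. = FALSE)
  }
  m <- regmatches(token, regexec("^([a-z]+)([0-9]{8})$", token))[[1]]
  if (length(m) != 3) {
    stop("malformed token: expected word followed by 8 digits",
         call. = FALSE)
  }
  word <- m[2]
  code <- as.integer(substr(m[3], 1, 5))
  mac <- as.integer(substr(m[3], 6, 8))
  n <- .blind_space(ranges)
  if (code >= n) stop("authentication failure: token does not decode under this key",
                      call. = FALSE)
  perm <- .blind_perm(key, n)
  idx <- match(code + 1, perm) - 1
  words <- .blind_wordlist()
  ok_mac <- mac == .eth_hash("mac", key, idx) %% 1000
  ok_word <- word == words[.eth_hash("word", key, idx) %% length(words) + 1]
  if (!ok_mac || !ok_word) {
    stop("authentication failure: token does not decode under this key",
         call. = FALSE)
  }
  trial <- idx %% ranges[3] + 1
  rest <- idx %/% ranges[3]
  session <- rest %% ranges[2] + 1
  rat <- rest %/% ranges[2] + 1
  list(rat_id = as.integer(rat), session_id = as.integer(session),
       trial_index = as.integer(trial))
}
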