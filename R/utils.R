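# Internal utilities: deterministic seed fan-out, config hashing, RNG
# hygiene.  All randomness in the package flows through derive_seed() so a
# single master seed reproduces every stage, group and repeat exactly.

# 32-bit FNV-1a over a character string, done in double arithmetic split
# into 16-bit halves so no intermediate exceeds 2^53.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor for non-negative doubles < 2^32
bitwXor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(floor(a / 65536) %% 65536, floor(b / 65536) %% 65536)
  hi * 65536 + lo
}

#' Derive a reproducible child seed
#'
#' Stable hash of a master seed plus any number of string/numeric tags,
#' mapped into the valid range for [set.seed()]. Used to fan one master
#' seed out to every stochastic stage (model fits, holdout repeats,
#' scenario draws) without correlated streams.
#'
#' @param master integer master seed.
#' @param ... tags (stage name, group label, repeat index, ...) coerced to
#'   character.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                       character(1)), collapse = "|")
  as.integer(fnv1a32(paste0(format(master), "::", tags)) %% 2147483647)
}

#' Hash a configuration object
#'
#' Deterministic 32-bit hash of a (nested) list, recorded in run manifests
#' for provenance.
#'
#' @param x any R object that [deparse()] can serialize.
#' @return hex string.
#' @export
config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x, control = "all"), collapse = "\n"))
  lo <- as.integer(h %% 65536)
  hi <- as.integer((h - lo) / 65536)
  sprintf("%04x%04x", hi, lo)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Write a data.frame as CSV with full-precision numerics ("%.17g") so a
# read-back reproduces every double bit-exactly.
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
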