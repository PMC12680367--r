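# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

vec_norm <- function(v) sqrt(sum(v^2))

# Row-wise Euclidean norms of an n x 2 matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# 90-degree CCW rotation of a 2-vector (the gradient of atan2 uses it).
perp <- function(v) c(-v[2], v[1])

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge user overrides into a nested default list: recursively by name for
# named lists, positionally for unnamed lists of lists of equal length
# (e.g. per-cell overrides).
modify_list_deep <- function(base, overrides) {
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (is.list(ov) && is.list(base[[nm]]) && !is.null(names(ov))) {
      base[[nm]] <- modify_list_deep(base[[nm]], ov)
    } else if (is.list(ov) && is.list(base[[nm]]) && is.null(names(ov)) &&
               length(ov) == length(base[[nm]]) && length(ov) > 0 &&
               all(vapply(ov, is.list, logical(1)))) {
      base[[nm]] <- Map(modify_list_deep, base[[nm]], ov)
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
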