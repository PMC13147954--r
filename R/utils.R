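# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' For each query point, is any target point within `radius` micrometres?
#'
#' Plain Euclidean all-pairs predicate; both point sets are assumed to come
#' from the same FOV (callers enforce the per-FOV contract).
#' @noRd
.any_within_radius <- function(xq, yq, xt, yt, radius) {
  if (length(xt) == 0L) return(rep(FALSE, length(xq)))
  d2 <- outer(xq, xt, "-")^2 + outer(yq, yt, "-")^2
  rowSums(d2 <= radius^2) > 0
}

# deterministic per-stage seed derivation: mixing the stage name into the
# global seed keeps each stage's stream independent of stage ordering
.derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 10007 + h * 7919) %% 2147483647)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
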