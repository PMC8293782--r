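#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state afterwards, so simulation functions are deterministic without
#' clobbering the session's random stream.
#'
#' @param seed Integer seed (required, finite).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a finite integer `seed` is required; simulations must be reproducible",
         call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a parent seed and indices
#'
#' Deterministic mixing that stays inside 32-bit integer range, used to give
#' every simulated trial / background segment its own reproducible stream.
#'
#' @param seed Parent seed.
#' @param ... Integer indices to mix in.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (k in seq_along(idx)) {
    s <- (s * 7919 + as.numeric(idx[k]) * 104729 + k) %% m
  }
  as.integer(max(1, s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge possibly overlapping intervals
#' @param start,end Numeric vectors of interval bounds.
#' @return A two-column matrix of disjoint intervals, sorted by start.
#' @keywords internal
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  cbind(start = out_s, end = out_e)
}

#' Membership of time points in a set of disjoint intervals
#' @param t Numeric vector of times.
#' @param intervals Matrix from [merge_intervals()].
#' @return Logical vector, TRUE where `t` lies inside `[start, end)`.
#' @keywords internal
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, intervals[, "start"])
  idx > 0 & t < intervals[cbind(pmax(idx, 1L), 2L)]
}

# Adjusted means of an exact (zero-residual) fit are well defined; muffle
# only the lm-summary precision caveat, leave every other warning intact.
muffle_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Stable CSV writer: fixed field order, no row names, full precision.
write_csv_stable <- function(x, path) {
  utils::write.csv(format(x, trim = TRUE, digits = 15, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
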