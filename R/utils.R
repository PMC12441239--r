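#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate expr, muffling "using fallback" lookup warnings and collecting
# their unique messages, so callers can log them once instead of per tree.
collect_fallbacks <- function(expr) {
  notes <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    msg <- conditionMessage(w)
    if (grepl("fallback", msg, fixed = TRUE)) {
      notes <<- union(notes, msg)
      invokeRestart("muffleWarning")
    }
  })
  list(value = val, notes = notes)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units; 1 for
#' identical partitions (up to label permutation), about 0 for independent
#' ones. Used to score recovery of planted stand types by the classifier.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
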