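#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones. Used to evaluate planted-module recovery.
#'
#' @param a,b label vectors; when both are named they are aligned by name.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) != length(a) || length(common) != length(b)) {
      stop("partitions cover different node sets")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("partitions have different lengths")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic per-stage seed below 2^31, derived from a global seed and a
# stage name so that stages are reproducible independently of each other.
stage_seed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  h <- as.double(seed %% 2147483647L)
  for (c in chars) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
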