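#' Adjusted Rand index between two partitions
#'
#' Measures agreement of two cluster assignments of the same cells,
#' corrected for chance; 1 means identical partitions (up to relabelling),
#' 0 is the expectation for independent labellings.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}

jaccard_index <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# FNV-1a hash of a serialized R object; used for config fingerprints in
# pipeline manifests (no external digest dependency).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  # skip serialization header (platform-dependent bytes are absent in v2
  # workspace format apart from the leading metadata)
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_sf <- function(msg, class) {
  stop(structure(class = c(class, "statefate_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
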