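# Multi-set overlap accounting, Jaccard similarity and clustering order.

# Extract a key vector from a CallSet, GoldenSet, VariantGroup, variant table
# or plain character vector of keys.
as_key_set <- function(x) {
  if (inherits(x, "VariantGroup")) x <- x$pooled
  if (inherits(x, c("CallSet", "GoldenSet"))) return(x$variants$key)
  if (is.data.frame(x)) return(x$key)
  as.character(x)
}

named_key_sets <- function(sets) {
  keys <- lapply(sets, as_key_set)
  nm <- names(sets)
  auto <- vapply(sets, function(x) {
    if (inherits(x, "VariantGroup")) x$label
    else if (inherits(x, "CallSet")) x$name
    else NA_character_
  }, "")
  if (is.null(nm)) nm <- auto
  nm[is.na(nm) | !nzchar(nm)] <- auto[is.na(nm) | !nzchar(nm)]
  blank <- is.na(nm) | !nzchar(nm)
  nm[blank] <- paste0("set", which(blank))
  stats::setNames(keys, nm)
}

#' Tally every intersection region of 2 to 6 variant sets
#'
#' Assigns each variant of the union to exactly one membership pattern (the
#' subset of input sets containing it) and counts the patterns. Patterns are
#' encoded as bitmask strings over the ordered set names (`"10"` = first set
#' only); all `2^k - 1` non-empty patterns are reported, including zero
#' counts. Percentages are counts over the union size.
#'
#' @param sets 2 to 6 named variant collections (`CallSet`s, `VariantGroup`s,
#'   variant tables or key vectors).
#' @return A `VennTally`: list with `set_names` and a data.frame `patterns`
#'   with columns `pattern` (bitmask), `sets` (`" & "`-joined names), `count`
#'   and `percentage`.
#' @export
venn_tally <- function(sets) {
  keys <- named_key_sets(sets)
  k <- length(keys)
  if (k < 2 || k > 6)
    stop(sprintf("venn_tally supports 2 to 6 sets, got %d", k))
  union_keys <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(s) union_keys %in% s,
                   logical(length(union_keys)))
  if (length(union_keys) == 1) member <- matrix(member, nrow = 1)
  if (length(union_keys) == 0) member <- matrix(logical(), ncol = k)
  # bitmask per union variant, first set = leftmost bit
  mask_of <- function(bits) paste(as.integer(bits), collapse = "")
  masks <- apply(member, 1, mask_of)
  all_masks <- vapply(seq_len(2^k - 1), function(m) {
    mask_of(bitwAnd(m, 2^((k - 1):0)) > 0)
  }, "")
  counts <- stats::setNames(integer(length(all_masks)), all_masks)
  tt <- table(masks)
  counts[names(tt)] <- as.integer(tt)
  total <- length(union_keys)
  set_names <- names(keys)
  pattern_sets <- vapply(all_masks, function(m) {
    paste(set_names[strsplit(m, "")[[1]] == "1"], collapse = " & ")
  }, "")
  structure(list(
    set_names = set_names,
    patterns = data.frame(pattern = all_masks, sets = unname(pattern_sets),
                          count = unname(counts),
                          percentage = if (total > 0) unname(counts) / total
                                       else rep(0, length(counts)),
                          stringsAsFactors = FALSE),
    total = total), class = "VennTally")
}

#' @export
print.VennTally <- function(x, ...) {
  cat(sprintf("<VennTally> %d sets, union of %d variants\n",
              length(x$set_names), x$total))
  print(x$patterns, row.names = FALSE)
  invisible(x)
}

#' Intersection of all sets
#'
#' @param sets one or more variant collections.
#' @return A variant table of the keys present in every set, sorted;
#'   exportable with [write_variants_vcf()].
#' @export
intersection_all <- function(sets) {
  keys <- named_key_sets(sets)
  if (length(keys) == 0) stop("intersection_all needs at least one set")
  inter <- Reduce(intersect, keys)
  sort_variant_table(keys_to_table(inter))
}

#' Jaccard similarity of two variant sets
#'
#' The number of variants in the intersection divided by the number in the
#' union, a score in \[0, 1\]. Undefined (an error) when both sets are empty.
#'
#' @param a,b variant collections.
#' @return A single numeric score.
#' @export
jaccard <- function(a, b) {
  a <- unique(as_key_set(a)); b <- unique(as_key_set(b))
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard similarity is undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix
#'
#' @param sets two or more named variant collections, all non-empty.
#' @return A `SimilarityMatrix`: symmetric numeric matrix with unit diagonal,
#'   labels as dimnames.
#' @export
jaccard_matrix <- function(sets) {
  keys <- named_key_sets(sets)
  if (length(keys) < 2) stop("jaccard_matrix needs at least two sets")
  empty <- names(keys)[lengths(keys) == 0]
  if (length(empty) > 0)
    stop(sprintf("Jaccard similarity is undefined for empty set(s): %s",
                 paste(empty, collapse = ", ")))
  k <- length(keys)
  m <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      m[i, j] <- m[j, i] <- jaccard(keys[[i]], keys[[j]])
    }
  }
  dimnames(m) <- list(names(keys), names(keys))
  structure(m, class = c("SimilarityMatrix", class(m)))
}

#' Hierarchical clustering order for a similarity matrix
#'
#' Agglomerative clustering on the distance `1 - J` with average linkage
#' (UPGMA), as used to order clustergram rows and columns. The leaf order is
#' deterministic; [stats::hclust()] breaks ties by input order. The same
#' order applies to rows and columns.
#'
#' @param m a `SimilarityMatrix`.
#' @return A list with `labels`, `order` (leaf indices), `merge` and `height`
#'   (the dendrogram merge list) and the underlying `hclust` object.
#' @export
cluster_order <- function(m) {
  if (nrow(m) < 2) stop("cluster_order needs at least two labels")
  d <- stats::as.dist(1 - unclass(m))
  hc <- stats::hclust(d, method = "average")
  list(labels = rownames(m), order = hc$order, merge = hc$merge,
       height = hc$height, hclust = hc)
}
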