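# Metadata-driven grouping: partition call sets by metadata column values and
# pool each group's variants by union, intersection or strict majority.

#' Specify how to group compare-set files
#'
#' @param group_by non-empty character vector of metadata property columns
#'   whose value tuples define the groups.
#' @param combine pooling method: `"union"` (variant in any member),
#'   `"intersection"` (in all members) or `"majority"` (in strictly more than
#'   half of the members; a tie at exactly 50 percent is excluded).
#' @param label_columns property columns used for display labels; defaults to
#'   `group_by`.
#' @return A `GroupSpec` list.
#' @export
group_spec <- function(group_by,
                       combine = c("union", "intersection", "majority"),
                       label_columns = group_by) {
  if (length(group_by) == 0) stop("group_by must name at least one column")
  structure(list(group_by = as.character(group_by),
                 combine = match.arg(combine),
                 label_columns = as.character(label_columns)),
            class = "GroupSpec")
}

pool_keys <- function(key_sets, combine) {
  all_keys <- unique(unlist(key_sets, use.names = FALSE))
  if (length(all_keys) == 0) return(character())
  hits <- Reduce(`+`, lapply(key_sets, function(k) all_keys %in% k))
  switch(combine,
         union = all_keys,
         intersection = all_keys[hits == length(key_sets)],
         majority = all_keys[hits > 0.5 * length(key_sets)])
}

#' Group call sets by metadata and pool their variants
#'
#' Files sharing the same value tuple in the `group_by` columns form one
#' group; each group's variants are pooled by the spec's combine method.
#' Groups are returned ordered by their key tuples so downstream tables and
#' figures are deterministic. Pooled call sets carry no filter status
#' (grouping happens after PASS filtering in the pipeline).
#'
#' @param callsets list of `CallSet`s whose names appear in `meta$FILENAME`.
#' @param meta a `MetadataTable` (see [read_metadata()]).
#' @param spec a [group_spec()].
#' @return A list of `VariantGroup`s, each with fields `key` (named character
#'   vector of group_by values), `label`, `members` (member call sets) and
#'   `pooled` (the combined `CallSet`).
#' @export
make_groups <- function(callsets, meta, spec) {
  missing_cols <- setdiff(spec$group_by, metadata_columns(meta))
  if (length(missing_cols) > 0)
    schema_error(sprintf("unknown group_by column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  cs_names <- vapply(callsets, function(cs) cs$name, "")
  absent <- setdiff(cs_names, meta$FILENAME)
  if (length(absent) > 0)
    coverage_error(sprintf("call set(s) not in metadata: %s",
                           paste(absent, collapse = ", ")))
  rows <- match(cs_names, meta$FILENAME)
  key_df <- meta[rows, spec$group_by, drop = FALSE]
  key_str <- do.call(paste, c(unname(as.list(key_df)), sep = "\r"))
  groups <- lapply(withr::with_collate("C", sort(unique(key_str))),
                   function(k) {
    idx <- which(key_str == k)
    members <- callsets[idx]
    keys <- pool_keys(lapply(members, function(cs) cs$variants$key),
                      spec$combine)
    key_vals <- stats::setNames(as.character(key_df[idx[1], ]), spec$group_by)
    g <- structure(list(key = key_vals, members = members,
                        pooled = NULL, label = NULL),
                   class = "VariantGroup")
    g$label <- group_label(g, spec$label_columns)
    g$pooled <- call_set(g$label,
                         sort_variant_table(keys_to_table(keys)))
    g
  })
  labels <- vapply(groups, function(g) g$label, "")
  if (anyDuplicated(labels))
    warning(sprintf("group labels collide after column subsetting: %s",
                    paste(unique(labels[duplicated(labels)]),
                          collapse = ", ")))
  groups
}

#' Display label for a variant group
#'
#' Joins the group's values in the chosen label columns, in column order,
#' with `" & "` (e.g. `"BWA & Strelka"`). An empty `label_columns` falls back
#' to the full group key.
#'
#' @param g a `VariantGroup`.
#' @param label_columns character vector of group_by columns to show.
#' @return A single display string.
#' @export
group_label <- function(g, label_columns = character()) {
  cols <- intersect(names(g$key), label_columns)
  if (length(cols) == 0) cols <- names(g$key)
  paste(g$key[cols], collapse = " & ")
}

#' @export
print.VariantGroup <- function(x, ...) {
  cat(sprintf("<VariantGroup> %s: %d member(s), %d pooled variants\n",
              x$label, length(x$members), n_variants(x$pooled)))
  invisible(x)
}
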