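# Orchestration of one analysis request, in the fixed stage order:
# validate -> load -> PASS filter -> region filter -> chrom/type filter ->
# group -> analyze -> export.  If any input fails to load, no analysis stage
# runs and the run log carries the error report.

#' Describe one analysis request
#'
#' @param compare_paths character vector of compare-set VCF paths (required).
#' @param analysis one of `"summary"`, `"venn"`, `"clustergram"`, `"pr"`,
#'   `"filter"` (`"filter"` writes one filtered, compressed VCF per input
#'   instead of running an analysis).
#' @param golden_paths golden-set VCF paths (required for `"pr"`).
#' @param metadata_path optional metadata CSV path.
#' @param region_paths optional BED paths.
#' @param pass_only keep only FILTER == "PASS" variants before analysis.
#' @param region_mode `"inside"`, `"outside"` or `NULL` (no region filter);
#'   requires `region_paths`.
#' @param vtype optional variant-type filter (`"snp"`/`"indel"`).
#' @param chroms optional chromosome whitelist.
#' @param group_spec optional [group_spec()]; requires `metadata_path`.
#' @param style a [style_spec()].
#' @param output_dir directory for result files (created if needed).
#' @param max_file_size per-file size limit in bytes.
#' @return An `AnalysisRequest` list.
#' @export
analysis_request <- function(compare_paths,
                             analysis = c("summary", "venn", "clustergram",
                                          "pr", "filter"),
                             golden_paths = character(),
                             metadata_path = NULL,
                             region_paths = character(),
                             pass_only = FALSE,
                             region_mode = NULL,
                             vtype = NULL,
                             chroms = NULL,
                             group_spec = NULL,
                             style = style_spec(),
                             output_dir = ".",
                             max_file_size = 200 * 1024^2) {
  analysis <- match.arg(analysis)
  if (length(compare_paths) == 0)
    stop("compare_paths must name at least one VCF file")
  if (analysis == "pr" && length(golden_paths) == 0)
    stop("analysis 'pr' requires golden_paths")
  if (!is.null(group_spec) && is.null(metadata_path))
    stop("grouping requires metadata_path")
  if (!is.null(region_mode))
    region_mode <- match.arg(region_mode, c("inside", "outside"))
  if (!is.null(region_mode) && length(region_paths) == 0)
    stop("region_mode requires region_paths")
  if (!is.null(vtype)) vtype <- match.arg(vtype, c("snp", "indel"))
  structure(list(compare_paths = compare_paths, analysis = analysis,
                 golden_paths = golden_paths, metadata_path = metadata_path,
                 region_paths = region_paths, pass_only = isTRUE(pass_only),
                 region_mode = region_mode, vtype = vtype, chroms = chroms,
                 group_spec = group_spec, style = style,
                 output_dir = output_dir, max_file_size = max_file_size),
            class = "AnalysisRequest")
}

log_note <- function(log, ...) {
  log$messages <- c(log$messages, sprintf(...))
  log
}

#' Run an analysis request
#'
#' Executes the loading and analysis stages in order. Loading errors are
#' collected per file; if any input fails, no analysis runs, no outputs are
#' written and the run log reports every error. On success the requested
#' analysis's PNG/CSV/VCF outputs are written under the request's
#' `output_dir`.
#'
#' @param request an [analysis_request()].
#' @return A `RunLog`: list with `ok`, `errors` (per-file messages),
#'   `warnings`, `messages`, `tallies` (per-set variant counts before/after
#'   each filter stage) and `outputs` (paths written).
#' @export
run_analysis <- function(request) {
  log <- list(ok = FALSE, errors = character(), warnings = character(),
              messages = character(), tallies = NULL,
              outputs = character())
  collect <- function(expr) {
    tryCatch(list(value = expr, error = NULL),
             vcfcompare_error = function(e)
               list(value = NULL, error = conditionMessage(e)),
             error = function(e)
               list(value = NULL, error = conditionMessage(e)))
  }

  # ---- stage 1: load everything, collecting errors --------------------------
  callsets <- list()
  for (p in request$compare_paths) {
    r <- collect(read_vcf(p, request$max_file_size))
    if (is.null(r$error)) callsets[[length(callsets) + 1L]] <- r$value
    else log$errors <- c(log$errors, r$error)
  }
  golden <- NULL
  if (length(request$golden_paths) > 0) {
    r <- collect(read_golden(request$golden_paths, request$max_file_size))
    if (is.null(r$error)) golden <- r$value
    else log$errors <- c(log$errors, r$error)
  }
  regions <- NULL
  if (length(request$region_paths) > 0) {
    r <- collect(read_bed(request$region_paths))
    if (is.null(r$error)) {
      regions <- r$value
      log <- log_note(log, "loaded %d genomic regions", n_regions(regions))
    } else log$errors <- c(log$errors, r$error)
  }
  meta <- NULL
  if (!is.null(request$metadata_path)) {
    r <- collect(read_metadata(request$metadata_path,
                               basename(request$compare_paths)))
    if (is.null(r$error)) meta <- r$value
    else log$errors <- c(log$errors, r$error)
  }
  if (length(log$errors) > 0) {
    class(log) <- "RunLog"
    return(log)
  }

  # disjoint chromosome name sets usually mean a naming-convention mismatch
  cmp_chroms <- unique(unlist(lapply(callsets,
                                     function(cs) unique(cs$variants$chrom))))
  warn_disjoint <- function(other, what) {
    if (length(other) > 0 && length(cmp_chroms) > 0 &&
        length(intersect(cmp_chroms, other)) == 0)
      log$warnings <<- c(log$warnings, sprintf(
        "compare-set and %s chromosome names are disjoint (e.g. '%s' vs '%s'); chromosomes match by exact string",
        what, cmp_chroms[1], other[1]))
  }
  if (!is.null(golden))
    warn_disjoint(unique(golden$variants$chrom), "golden-set")
  if (!is.null(regions))
    warn_disjoint(unique(regions$intervals$chrom), "region")

  # ---- stage 2: filters in fixed order: PASS -> regions -> chrom/type -------
  tallies <- data.frame(name = vapply(callsets, function(cs) cs$name, ""),
                        loaded = vapply(callsets, n_variants, 0L),
                        stringsAsFactors = FALSE)
  if (request$pass_only) {
    callsets <- lapply(callsets, filter_pass)
    tallies$pass <- vapply(callsets, n_variants, 0L)
  }
  if (!is.null(request$region_mode)) {
    callsets <- lapply(callsets, filter_regions_sorted, rs = regions,
                       mode = request$region_mode)
    tallies$regions <- vapply(callsets, n_variants, 0L)
  }
  if (!is.null(request$chroms)) {
    callsets <- lapply(callsets, filter_chromosomes, chroms = request$chroms)
    tallies$chrom <- vapply(callsets, n_variants, 0L)
  }
  if (!is.null(request$vtype)) {
    callsets <- lapply(callsets, filter_variant_type, vtype = request$vtype)
    tallies$vtype <- vapply(callsets, n_variants, 0L)
  }
  log$tallies <- tallies

  # ---- stage 3: grouping ----------------------------------------------------
  items <- callsets
  if (!is.null(request$group_spec)) {
    r <- collect(withCallingHandlers(
      make_groups(callsets, meta, request$group_spec),
      warning = function(w) {
        log$warnings <<- c(log$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
    if (!is.null(r$error)) {
      log$errors <- c(log$errors, r$error)
      class(log) <- "RunLog"
      return(log)
    }
    items <- r$value
  }

  # ---- stage 4: analysis + export ------------------------------------------
  out <- function(f) file.path(request$output_dir, f)
  dir.create(request$output_dir, showWarnings = FALSE, recursive = TRUE)
  r <- collect(switch(request$analysis,
    filter = {
      vapply(callsets, function(cs) {
        vcf <- out(paste0(tools::file_path_sans_ext(cs$name, compression = TRUE),
                          ".filtered.vcf.gz"))
        write_variants_vcf(cs$variants, vcf)
        vcf
      }, "")
    },
    summary = {
      counts <- count_table(items)
      paths <- render_histogram(counts, out("variant_counts.png"),
                                request$style)
      unlist(paths)
    },
    venn = {
      n <- length(items)
      if (n < 2 || n > 6)
        stop(sprintf(
          "Venn analysis requires 2 to 6 sets after grouping, got %d", n))
      tally <- venn_tally(items)
      paths <- render_venn(tally, out("venn.png"), request$style)
      inter <- intersection_all(items)
      vcf <- out("intersection.vcf.gz")
      write_variants_vcf(inter, vcf)
      c(unlist(paths), intersection = vcf)
    },
    clustergram = {
      m <- jaccard_matrix(items)
      ord <- cluster_order(m)
      ann <- NULL
      if (!is.null(meta) && is.null(request$group_spec)) {
        cols <- c(request$style$color_by)
        if (length(cols) > 0) {
          ann <- meta[match(rownames(m), meta$FILENAME), cols,
                      drop = FALSE]
          rownames(ann) <- rownames(m)
        }
      }
      paths <- render_clustergram(m, ord, out("clustergram.png"),
                                  request$style, annotations = ann)
      unlist(paths)
    },
    pr = {
      if (is.null(golden) || n_variants(golden) == 0)
        stop("benchmarking requires a non-empty golden set")
      results <- benchmark_many(items, golden)
      paths <- render_pr_plot(results, out("precision_recall.png"),
                              request$style, meta = meta)
      unlist(paths)
    }))
  if (!is.null(r$error)) {
    log$errors <- c(log$errors, r$error)
  } else {
    log$outputs <- r$value
    log$ok <- TRUE
  }
  class(log) <- "RunLog"
  log
}

#' @export
print.RunLog <- function(x, ...) {
  cat(sprintf("<RunLog> %s\n", if (x$ok) "ok" else "failed"))
  if (length(x$errors) > 0)
    cat(paste0("  error: ", x$errors, collapse = "\n"), "\n")
  if (length(x$warnings) > 0)
    cat(paste0("  warning: ", x$warnings, collapse = "\n"), "\n")
  if (!is.null(x$tallies)) {
    cat("  filter tallies:\n")
    print(x$tallies, row.names = FALSE)
  }
  if (length(x$outputs) > 0)
    cat(paste0("  wrote: ", x$outputs, collapse = "\n"), "\n")
  invisible(x)
}
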