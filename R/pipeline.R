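# End-to-end orchestration: subsets -> gap statistics -> distances -> site
# rates -> region statistics -> indels/deletion -> test battery, written as
# a TSV report bundle with a JSON manifest.
#
# Per-clade analyses reuse the master coordinate system (rows are
# subsetted, columns are not compacted): all-gap columns fall below the
# coverage threshold and drop out of every rate statistic on their own,
# while region annotations stay valid.  Compacted subset alignments are
# used only for the alignment-level gap statistics.

#' Assemble an analysis configuration
#'
#' @param alignment Path to an aligned FASTA file, or an alignment matrix.
#' @param groups Path to a taxon/clade TSV, or a named character vector.
#' @param regions Path to a region TSV, or a [region_set()].
#' @param out_dir Output directory for the report bundle.
#' @param coverage_threshold Minimum site coverage (default 0.15).
#' @param rolling_window Rolling-average window for the rate profile
#'   (default 35).
#' @param alpha Nominal test level recorded in the manifest (default 0.05;
#'   no multiple-testing correction is applied).
#' @param deletion_win Named vector \code{c(start, length)} or NULL to
#'   derive it from the 3' end of region V3 via [deletion_window()].
#' @param exemplars Taxon ids whose per-region indel summaries are
#'   tabulated; default: the first taxon of each clade.
#' @param structure_maps Optional named list of [structure_map()] objects in
#'   master alignment coordinates, keyed by dataset name (\code{"all"} or a
#'   clade label), enabling the paired/stem-loop tests.
#' @param gtr_distances Also compute GTR maximum-likelihood distances
#'   (default TRUE).
#' @param outgroup Clade label excluded from the rate datasets (e.g. an
#'   outgroup lineage); NULL to use every taxon.
#' @return List of class \code{analysis_config}.
#' @export
analysis_config <- function(alignment, groups, regions, out_dir,
                            coverage_threshold = 0.15,
                            rolling_window = 35L, alpha = 0.05,
                            deletion_win = NULL, exemplars = NULL,
                            structure_maps = NULL, gtr_distances = TRUE,
                            outgroup = NULL) {
  structure(list(alignment = alignment, groups = groups, regions = regions,
                 out_dir = out_dir, coverage_threshold = coverage_threshold,
                 rolling_window = as.integer(rolling_window), alpha = alpha,
                 deletion_win = deletion_win, exemplars = exemplars,
                 structure_maps = structure_maps,
                 gtr_distances = gtr_distances, outgroup = outgroup),
            class = "analysis_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full variability analysis
#'
#' Executes every stage on the configured alignment and writes a report
#' bundle to the output directory: \code{table1_distances.tsv},
#' \code{table2_gaps.tsv}, \code{table3_rates.tsv},
#' \code{table4_tests.tsv}, \code{table5_indels.tsv},
#' \code{table6_site_classes.tsv}, \code{rates_<dataset>.tsv} (per-column
#' rates with rolling means), \code{deletion_report.tsv}, optional Vienna
#' structure files, and \code{manifest.json} with the resolved
#' configuration, per-stage timings and any failure point.  Output is
#' deterministic given the configuration.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with all computed tables and the manifest.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- if (is.character(config$alignment)) read_aligned_fasta(config$alignment)
         else config$alignment
  groups <- if (is.character(config$groups) && length(config$groups) == 1L &&
                file.exists(config$groups)) read_groups(config$groups, aln)
            else config$groups[rownames(aln)]
  regions <- if (inherits(config$regions, "region_set")) config$regions
             else read_regions(config$regions)

  manifest <- list(package = "ssuvar",
                   version = as.character(utils::packageVersion("ssuvar")),
                   config = resolved_config(config, aln),
                   timings = list(), failure = NULL)
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) e)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(out, "error")) {
      manifest$failure <<- list(stage = name, message = conditionMessage(out))
      stop("stage '", name, "' failed: ", conditionMessage(out))
    }
    out
  }
  on.exit(jsonlite::write_json(manifest,
                               file.path(config$out_dir, "manifest.json"),
                               auto_unbox = TRUE, pretty = TRUE, digits = NA,
                               force = TRUE))

  clades <- unique(groups)
  rate_clades <- clades[table(groups)[clades] >= 4L]
  if (!is.null(config$outgroup)) {
    ingroup_taxa <- rownames(aln)[groups != config$outgroup]
    rate_clades <- setdiff(rate_clades, config$outgroup)
  } else ingroup_taxa <- rownames(aln)
  datasets <- c(list(all = ingroup_taxa),
                setNames(lapply(rate_clades,
                                function(cl) rownames(aln)[groups == cl]),
                         rate_clades))

  results$table2 <- stage("gap_statistics", {
    do.call(rbind, lapply(names(datasets), function(nm) {
      sub <- subset_and_compact(aln, datasets[[nm]])$aln
      gs <- gap_statistics(sub)
      data.frame(dataset = nm, n_taxa = nrow(sub),
                 aligned_length = gs$aligned_length,
                 internal_gap_cells = gs$internal_gap_cells,
                 assessed_cells = gs$assessed_cells,
                 pct_gaps = round(gs$pct_gaps, 2))
    }))
  })
  write_tsv(results$table2, file.path(config$out_dir, "table2_gaps.tsv"))

  results$table1 <- stage("distances", {
    Dp <- distance_matrix(aln, "p")
    write_tsv(cbind(taxon = rownames(Dp), as.data.frame(Dp)),
              file.path(config$out_dir, "pdist_matrix.tsv"))
    t1 <- group_summary(Dp, groups)
    t1$model <- "p"
    if (isTRUE(config$gtr_distances)) {
      Dg <- distance_matrix(aln, "GTR")
      tg <- group_summary(Dg, groups)
      tg$model <- "GTR"
      t1 <- rbind(t1, tg)
    }
    t1
  })
  write_tsv(results$table1, file.path(config$out_dir, "table1_distances.tsv"))

  results$rates <- stage("tiger_rates", {
    lapply(datasets, function(taxa)
      tiger_rates(aln[taxa, , drop = FALSE], config$coverage_threshold))
  })
  stage("rate_outputs", {
    for (nm in names(results$rates)) {
      rt <- results$rates[[nm]]
      rt$rolling_mean <- rolling_average(rt$rate, config$rolling_window)
      rt$region <- region_of(regions, rt$column)
      write_tsv(rt, file.path(config$out_dir,
                              paste0("rates_", nm, ".tsv")))
      write_tsv(rate_histogram(results$rates[[nm]]),
                file.path(config$out_dir, paste0("rate_hist_", nm, ".tsv")))
    }
    NULL
  })

  results$table3 <- stage("rate_summaries", {
    do.call(rbind, lapply(names(results$rates), function(nm) {
      a <- summarize_rates(results$rates[[nm]], "all")
      v <- summarize_rates(results$rates[[nm]], "variable_only")
      data.frame(dataset = nm,
                 mean_all = a$mean, se_all = a$se, n_all = a$n,
                 mean_variable = v$mean, se_variable = v$se,
                 n_variable = v$n)
    }))
  })
  write_tsv(results$table3, file.path(config$out_dir, "table3_rates.tsv"))

  results$table6 <- stage("site_classes", {
    do.call(rbind, lapply(names(results$rates), function(nm) {
      rt <- results$rates[[nm]]
      rated <- rt$class != "insufficient_coverage"
      hyper <- region_of(regions, rt$column) != "non-hypervariable"
      do.call(rbind, lapply(c(FALSE, TRUE), function(h) {
        sel <- rated & (hyper == h)
        data.frame(dataset = nm,
                   region = if (h) "hypervariable" else "non-hypervariable",
                   total = sum(sel),
                   constant = sum(rt$class[sel] == "constant"),
                   variable = sum(rt$class[sel] == "variable"))
      }))
    }))
  })
  write_tsv(results$table6, file.path(config$out_dir,
                                      "table6_site_classes.tsv"))

  results$table5 <- stage("indels", {
    exemplars <- config$exemplars
    if (is.null(exemplars))
      exemplars <- vapply(rate_clades, function(cl)
        rownames(aln)[groups == cl][1L], character(1))
    do.call(rbind, lapply(exemplars, function(tx)
      region_indel_summary(aln[ingroup_taxa, , drop = FALSE], tx, regions)))
  })
  write_tsv(results$table5, file.path(config$out_dir, "table5_indels.tsv"))

  results$deletion <- stage("deletion", {
    win <- config$deletion_win
    if (is.null(win) && "V3" %in% regions$name) {
      win <- deletion_window(regions, "V3")
      # keep the derived window inside the alignment
      win[["length"]] <- min(win[["length"]],
                             ncol(aln) - win[["start"]] + 1L)
    }
    if (is.null(win)) NULL
    else detect_deletion(aln, win, groups = groups)
  })
  if (!is.null(results$deletion))
    write_tsv(results$deletion, file.path(config$out_dir,
                                          "deletion_report.tsv"))

  results$table4 <- stage("tests", {
    rows <- list()
    for (nm in names(results$rates)) {
      sm <- config$structure_maps[[nm]]
      bat <- run_test_battery(results$rates[[nm]], sm, regions)
      for (tn in names(bat)) {
        tr <- bat[[tn]]
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = nm, comparison = tn, test = tr$test,
          statistic = tr$statistic, Z = tr$Z, df = tr$df, p = tr$p,
          n = paste(tr$n, collapse = "/"),
          note = ifelse(is.na(tr$note), "", tr$note))
      }
    }
    do.call(rbind, rows)
  })
  write_tsv(results$table4, file.path(config$out_dir, "table4_tests.tsv"))

  if (!is.null(config$structure_maps))
    stage("structures", {
      write_vienna(config$structure_maps,
                   file.path(config$out_dir, "structures.vienna"))
    })

  invisible(c(results, list(manifest = manifest)))
}

resolved_config <- function(config, aln) {
  list(n_taxa = nrow(aln), aligned_length = ncol(aln),
       coverage_threshold = config$coverage_threshold,
       rolling_window = config$rolling_window, alpha = config$alpha,
       gtr_distances = isTRUE(config$gtr_distances),
       outgroup = if (is.null(config$outgroup)) NA else config$outgroup,
       deletion_window = if (is.null(config$deletion_win)) "auto (V3 3' end)"
                         else paste(config$deletion_win, collapse = ","))
}
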