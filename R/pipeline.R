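.read_cfg <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(p_threshold = 5e-8, clump_r2 = 0.1,
                   palindrome_eaf_window = 0.08, decrement_percent = 30,
                   methods = c("ivw_fixed", "egger", "weighted_median",
                               "weighted_mode"),
                   n_boot = 1000L, seed = 1L, ld_path = NULL,
                   out_dir = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

.stage_stop <- function(stage, ...) stop("[", stage, "] ", ..., call. = FALSE)

.read_table_spec <- function(spec, default_type, stage) {
  if (is.null(spec$path)) .stage_stop(stage, "missing 'path'")
  if (!file.exists(spec$path)) .stage_stop(stage, "unreadable file: ",
                                           spec$path)
  cmap <- if (is.null(spec$column_map)) defaultColumnMap()
          else unlist(spec$column_map)
  readSumStats(spec$path, columnMap = cmap,
               traitType = if (is.null(spec$trait_type)) default_type
                           else spec$trait_type,
               traitLabel = if (is.null(spec$label)) basename(spec$path)
                            else spec$label)
}

.estimate_row <- function(outcome_label, role, est, q = NULL, egger = NULL,
                          het = NULL) {
  data.frame(outcome = outcome_label, role = role, method = est@method,
             n_variants = est@nVariants, beta = est@beta, se = est@se,
             or = est@or, ci_low = est@orLow, ci_high = est@orHigh,
             pvalue = est@pvalue,
             q = if (is.null(q)) NA_real_ else q@q,
             q_df = if (is.null(q)) NA_integer_ else q@df,
             q_p = if (is.null(q)) NA_real_ else q@pvalue,
             egger_intercept = if (is.null(egger)) NA_real_
                               else egger@intercept,
             egger_intercept_p = if (is.null(egger)) NA_real_
                                 else egger@interceptP,
             het_vs_control_q = if (is.null(het)) NA_real_ else het@q,
             het_vs_control_p = if (is.null(het)) NA_real_ else het@pvalue,
             stringsAsFactors = FALSE)
}

#' Run the full drug-target MR analysis from a config
#'
#' Orchestrates instrument construction (cis-window + significance filter,
#' optional LD clumping), allele harmonization against every outcome, the
#' requested estimator suite with Cochran Q and Egger-intercept
#' diagnostics, leave-one-out tables, decrement-scaled odds ratios, and a
#' between-estimate Cochran Q contrast of every outcome against the
#' positive control. Deterministic for a fixed config and seed.
#'
#' @param config a list or YAML file path with entries: `exposure`
#'   (`path`, optional `column_map`, `label`), `outcomes` (list of `path`,
#'   `label`, `trait_type`, `role` = `"primary"` or `"positive_control"`),
#'   `region` (`chrom`, `gene_start`, `gene_end`, optional `flank`),
#'   `p_threshold` (5e-8), `ld_path` (optional LD matrix file; clumping is
#'   skipped when absent), `clump_r2` (0.1), `palindrome_eaf_window`
#'   (0.08), `decrement_percent` (30), `methods`, `n_boot` (1000), `seed`,
#'   and optional `out_dir` for tidy TSV outputs.
#' @return list with `master` (tidy estimate table), `instruments`
#'   (selected exposure [SumStatTable-class]), `f_stats`,
#'   `variance_explained`, `leave_one_out` (per-outcome list), `harmonization`
#'   (per-outcome exclusion logs), and `config`.
#' @export
runAnalysis <- function(config) {
  cfg <- .read_cfg(config)
  if (is.null(cfg$exposure) || is.null(cfg$outcomes) || is.null(cfg$region))
    .stage_stop("config", "exposure, outcomes, and region are required")

  exposure <- .read_table_spec(cfg$exposure, "quantitative", "read_exposure")
  region <- cisRegion(cfg$region$chrom, cfg$region$gene_start,
                      cfg$region$gene_end,
                      if (is.null(cfg$region$flank)) 3e5 else cfg$region$flank)
  instruments <- selectCisVariants(exposure, region, cfg$p_threshold)
  if (!length(instruments))
    .stage_stop("select_instruments", "no variants survive the cis window ",
                "and significance threshold")
  if (!is.null(cfg$ld_path)) {
    ld <- readLDMatrix(cfg$ld_path)
    instruments <- ldClump(instruments, ld, cfg$clump_r2)
  }
  inst_d <- as.data.frame(instruments)
  f_stats <- stats::setNames(fStatistic(inst_d$beta, inst_d$se),
                             inst_d$variant_id)
  r2_explained <- if (all(!is.na(inst_d$eaf)))
    varianceExplained(instruments) else NA_real_
  scale <- decrementScale(cfg$decrement_percent)

  roles <- vapply(cfg$outcomes, function(o)
    if (is.null(o$role)) "primary" else o$role, character(1))
  n_primary <- sum(roles == "primary")
  bonf <- 0.05 / max(n_primary, 1)

  control_est <- NULL
  rows <- list(); loo <- list(); harm_logs <- list()
  results <- vector("list", length(cfg$outcomes))
  # process positive controls first so primary rows can carry the contrast
  ord <- c(which(roles == "positive_control"), which(roles == "primary"))
  for (i in ord) {
    ospec <- cfg$outcomes[[i]]
    label <- if (is.null(ospec$label)) basename(ospec$path) else ospec$label
    outcome <- .read_table_spec(ospec, "binary", paste0("read_outcome:",
                                                        label))
    h <- harmonize(instruments, outcome, cfg$palindrome_eaf_window)
    harm_logs[[label]] <- processingLog(h)
    nh <- nrow(as.data.frame(h))
    if (!nh) .stage_stop("harmonize", "no instruments harmonize against ",
                         label)
    primary <- if (nh == 1L) rescaleEstimate(waldRatio(h), scale)
               else rescaleEstimate(ivwFixed(h), scale)
    q <- if (nh >= 2L) cochranQ(h) else NULL
    egger <- if (nh >= 3L && "egger" %in% c(cfg$methods, "egger"))
      mrEgger(h) else NULL
    het <- if (!is.null(control_est) && roles[i] == "primary")
      betweenEstimateQ(primary, control_est) else NULL
    out_rows <- list(.estimate_row(label, roles[i], primary, q, egger, het))
    if (nh >= 3L) {
      if (any(c("egger", "egger_slope") %in% cfg$methods) && !is.null(egger))
        out_rows <- c(out_rows, list(.estimate_row(
          label, roles[i], rescaleEstimate(egger@slope, scale), q, egger)))
      if ("weighted_median" %in% cfg$methods)
        out_rows <- c(out_rows, list(.estimate_row(
          label, roles[i],
          rescaleEstimate(weightedMedian(h, cfg$n_boot, cfg$seed), scale))))
      if ("weighted_mode" %in% cfg$methods)
        out_rows <- c(out_rows, list(.estimate_row(
          label, roles[i],
          rescaleEstimate(weightedMode(h, nBoot = cfg$n_boot,
                                       seed = cfg$seed), scale))))
      loo[[label]] <- leaveOneOut(h)
    }
    results[[i]] <- do.call(rbind, out_rows)
    if (roles[i] == "positive_control" && is.null(control_est))
      control_est <- primary
  }
  # master table in config order, positive controls last
  master <- do.call(rbind, c(results[roles == "primary"],
                             results[roles == "positive_control"]))
  master$significant_bonferroni <- master$role == "primary" &
    master$pvalue < bonf
  rownames(master) <- NULL

  out <- list(master = master, instruments = instruments, f_stats = f_stats,
              variance_explained = r2_explained, leave_one_out = loo,
              harmonization = harm_logs, bonferroni_threshold = bonf,
              config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(master, file.path(cfg$out_dir, "master.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeSumStats(instruments, file.path(cfg$out_dir, "instruments.tsv"))
    for (label in names(loo))
      utils::write.table(loo[[label]],
                         file.path(cfg$out_dir,
                                   paste0("loo_", gsub("\\W+", "_", label),
                                          ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(renderForestTable(master),
               file.path(cfg$out_dir, "report.md"))
  }
  out
}

#' Render a forest-plot-style markdown table
#'
#' One row per outcome and method with the decrement-scaled OR and CI,
#' p-value, instrument count, and heterogeneity columns; rows keep the
#' master-table order (primary outcomes in config order, positive controls
#' last).
#'
#' @param master the tidy estimate table from [runAnalysis()].
#' @return character vector of markdown lines.
#' @export
renderForestTable <- function(master) {
  if (!nrow(master)) {
    warning("empty master table")
    return(character())
  }
  fmt_p <- function(p) ifelse(is.na(p), "", sprintf("%.3g", p))
  header <- c(
    "| Outcome | Role | Method | n SNPs | OR (95% CI) | P | Q (df) | P het | Egger intercept P |",
    "|---|---|---|---|---|---|---|---|---|")
  body <- vapply(seq_len(nrow(master)), function(i) {
    r <- master[i, ]
    sprintf("| %s | %s | %s | %d | %.2f [%.2f, %.2f] | %s | %s | %s | %s |",
            r$outcome, r$role, r$method, r$n_variants, r$or, r$ci_low,
            r$ci_high, fmt_p(r$pvalue),
            if (is.na(r$q)) "" else sprintf("%.2f (%d)", r$q, r$q_df),
            fmt_p(r$q_p), fmt_p(r$egger_intercept_p))
  }, character(1))
  c(header, body)
}
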