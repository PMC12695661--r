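# End-to-end orchestration over a dataset directory (as written by
# simulate_dataset() or assembled by the user with the same file schemas).
# Each stage writes its outputs as TSV/JSON; the run report records every
# threshold actually used plus a hash of the effective configuration.

#' Pipeline configuration
#'
#' Thresholds default to the package's standard values; any can be
#' overridden. The report logs the effective values so default-vs-override
#' is auditable.
#'
#' @param dataset_dir directory with `genes.tsv`, `counts.tsv`,
#'   `sample_sheet.tsv` and optionally `antisense_counts.tsv`,
#'   `ctcf_peaks.narrowPeak`, `rad21_peaks.narrowPeak`, `genome.fa`.
#' @param out_dir output directory.
#' @param treatment_minutes treatment duration for the counting cap (240 =
#'   full gene).
#' @param scheme regulation-class scheme.
#' @param thresholds named list overriding defaults (`low_count`,
#'   `low_count_antisense`, `tpm_expressed`, `fc_reproducibility`,
#'   `uastrx_fc`, `merge_min_n`).
#' @param seed integer seed for any stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset_dir, out_dir,
                            treatment_minutes = 30,
                            scheme = "standard",
                            thresholds = list(), seed = 1) {
  th <- modifyList(list(
    low_count = .eureg_defaults$low_count_threshold,
    low_count_antisense = .eureg_defaults$low_count_threshold_antisense,
    tpm_expressed = .eureg_defaults$tpm_expressed,
    fc_reproducibility = .eureg_defaults$fc_reproducibility,
    uastrx_fc = .eureg_defaults$uastrx_fc,
    merge_min_n = .eureg_defaults$merge_min_n
  ), thresholds)
  structure(list(dataset_dir = dataset_dir, out_dir = out_dir,
                 treatment_minutes = treatment_minutes, scheme = scheme,
                 thresholds = th, seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline on a dataset directory
#'
#' Executes: window derivation, TPM and expression filtering, size-factor
#' estimation, asymmetry-corrected differential fold changes, regulation
#' classification with small-class merging, per-replicate fold changes and
#' the reproducibility filter (when the sample sheet defines extra pairs),
#' antisense candidate calling (when antisense counts are present), and
#' promoter CTCF annotation with motif orientation (when peaks and genome
#' are present). Fails fast with a stage-naming error on invalid input.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the run report list (also written to
#'   `report.json` in `out_dir` alongside `differential.tsv` and
#'   `regulation_table.tsv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dd <- config$dataset_dir
  need <- c("genes.tsv", "counts.tsv", "sample_sheet.tsv")
  missing_files <- need[!file.exists(file.path(dd, need))]
  if (length(missing_files)) {
    stop("stage 'load': dataset is missing ",
         paste(missing_files, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds

  genes <- read_gene_models_tsv(file.path(dd, "genes.tsv"))
  counts <- read_counts_tsv(file.path(dd, "counts.tsv"))
  sheet <- read.table(file.path(dd, "sample_sheet.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  if (!all(sheet$sample %in% colnames(counts))) {
    stop("stage 'load': sample sheet names sample(s) absent from counts: ",
         paste(setdiff(sheet$sample, colnames(counts)), collapse = ", "))
  }
  counts <- counts[genes$gene_id, sheet$sample, drop = FALSE]
  initial <- sheet[is.na(sheet$pair) | sheet$pair == "", , drop = FALSE]
  if (!nrow(initial)) initial <- sheet

  win <- compute_counting_window(genes, config$treatment_minutes,
                                 full_gene = config$treatment_minutes == 240)
  tpm <- compute_tpm(counts, width(win))
  flags <- apply_expression_filters(counts[, initial$sample, drop = FALSE],
                                    tpm[, initial$sample, drop = FALSE],
                                    initial,
                                    low_count = th$low_count,
                                    tpm_expressed = th$tpm_expressed)
  expressed <- flags$gene_id[flags$expressed]
  if (!length(expressed)) stop("stage 'filter': no expressed genes")

  sf <- estimate_size_factors(counts)
  diffres <- compute_adjusted_log2fc(counts[, initial$sample, drop = FALSE],
                                     initial, expressed,
                                     size_factors = sf[initial$sample])

  labels <- rep(NA_character_, nrow(genes))
  ok <- genes$gene_id %in% expressed & !is.na(diffres$adjusted_log2fc)
  labels[ok] <- assign_class(2^diffres$adjusted_log2fc[ok], config$scheme)
  merged <- rep(NA_character_, nrow(genes))
  merged[ok] <- merge_small_classes(labels[ok], min_n = th$merge_min_n)

  reproducible <- rep(NA, nrow(genes))
  has_pairs <- any(!is.na(sheet$pair) & sheet$pair != "")
  rep_fc <- NULL
  if (has_pairs) {
    rep_fc <- per_replicate_log2fc(counts, sheet, expressed,
                                   size_factors = sf)
    dirn <- ifelse(diffres$adjusted_log2fc < 0, "down", "up")
    for (d in c("down", "up")) {
      i <- which(ok & dirn == d)
      if (length(i)) {
        reproducible[i] <- reproducibility_filter(
          diffres$adjusted_log2fc[i], rep_fc[i, , drop = FALSE],
          direction = d, fc_threshold = th$fc_reproducibility,
          per_replicate_threshold = th$fc_reproducibility)
      }
    }
  }

  uastrx <- character(0)
  anti_path <- file.path(dd, "antisense_counts.tsv")
  if (file.exists(anti_path)) {
    anti <- read_counts_tsv(anti_path)[genes$gene_id, initial$sample,
                                       drop = FALSE]
    aflags <- apply_expression_filters(anti, tpm[, initial$sample],
                                       initial,
                                       low_count = th$low_count_antisense,
                                       tpm_expressed = -Inf)
    included <- aflags$gene_id[!aflags$low_count_excluded]
    adiff <- compute_adjusted_log2fc(anti, initial, expressed,
                                     size_factors = sf[initial$sample])
    al2 <- setNames(adiff$adjusted_log2fc, adiff$gene_id)
    uastrx <- call_uastrx_up(al2, sense_expressed = expressed,
                             antisense_included = included,
                             threshold_fc = th$uastrx_fc)
  }

  annot <- NULL
  pk_path <- file.path(dd, "ctcf_peaks.narrowPeak")
  if (file.exists(pk_path)) {
    peaks <- read_narrowpeak(pk_path)
    rad_path <- file.path(dd, "rad21_peaks.narrowPeak")
    rad <- if (file.exists(rad_path)) read_narrowpeak(rad_path) else NULL
    annot <- annotate_promoter_peaks(peaks, genes, rad21_peaks = rad)
    fa <- file.path(dd, "genome.fa")
    if (file.exists(fa)) {
      b <- which(!is.na(annot$nearest_distance) & annot$in_400bp)
      if (length(b)) {
        ori <- classify_motif_orientation(
          data.frame(chrom = genes$chrom[b],
                     summit = ifelse(genes$strand[b] == "+",
                                     genes$tss[b] + annot$nearest_distance[b],
                                     genes$tss[b] - annot$nearest_distance[b])),
          genome = fa, pwm = ctcf_pwm(), gene_strand = genes$strand[b])
        annot$motif_orientation <- NA_character_
        annot$motif_orientation[b] <- ori$orientation
      }
    }
    write.table(annot, file.path(config$out_dir, "promoter_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  diff_out <- cbind(diffres,
                    mean_tpm_control = flags$mean_tpm_control,
                    mean_tpm_treatment = flags$mean_tpm_treatment,
                    expressed = flags$expressed)
  write.table(diff_out, file.path(config$out_dir, "differential.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- data.frame(gene_id = genes$gene_id, class = labels,
                    merged_class = merged,
                    grouping = regulation_grouping(labels),
                    reproducible = reproducible,
                    uastrx_up = genes$gene_id %in% uastrx)
  write.table(reg, file.path(config$out_dir, "regulation_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("eureg")),
    config_hash = .config_hash(config),
    thresholds = th,
    scheme = config$scheme,
    treatment_minutes = config$treatment_minutes,
    n_genes = nrow(genes),
    n_expressed = length(expressed),
    asymmetry_median = attr(diffres, "asymmetry_median"),
    size_factors = as.list(sf),
    class_counts = as.list(table(labels, useNA = "no")),
    n_reproducible = sum(reproducible, na.rm = TRUE),
    n_uastrx_candidates = length(uastrx)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset) and `run`
#' (run the pipeline on a dataset directory). Exit codes: 0 success, 2
#' validation error, 1 runtime error (applied by the wrapper script in
#' `inst/cli/eureg.R`).
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return Invisibly, the value of the subcommand.
#' @export
eureg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: eureg <simulate|run> [options]", call. = FALSE)
  }
  cmd <- args[1]
  rest <- args[-1]
  if (cmd == "simulate") {
    spec <- list(
      optparse::make_option("--out", type = "character"),
      optparse::make_option("--genes", type = "integer", default = 300L),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--force", action = "store_true",
                            default = FALSE),
      optparse::make_option("--fragments", action = "store_true",
                            default = FALSE)
    )
    opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                                args = rest)
    if (is.null(opt$out)) stop("simulate: --out is required", call. = FALSE)
    cfg <- simulation_config(n_genes = opt$genes, seed = opt$seed)
    invisible(simulate_dataset(cfg, opt$out, force = opt$force,
                               fragments = opt$fragments))
  } else if (cmd == "run") {
    spec <- list(
      optparse::make_option("--dataset", type = "character"),
      optparse::make_option("--out", type = "character"),
      optparse::make_option("--minutes", type = "integer", default = 30L),
      optparse::make_option("--scheme", type = "character",
                            default = "standard"),
      optparse::make_option("--seed", type = "integer", default = 1L)
    )
    opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                                args = rest)
    if (is.null(opt$dataset) || is.null(opt$out)) {
      stop("run: --dataset and --out are required", call. = FALSE)
    }
    invisible(run_pipeline(pipeline_config(
      opt$dataset, opt$out, treatment_minutes = opt$minutes,
      scheme = opt$scheme, seed = opt$seed)))
  } else {
    stop("unknown subcommand '", cmd, "'; use simulate or run",
         call. = FALSE)
  }
}
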