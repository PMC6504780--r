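#' Validate a pipeline configuration
#'
#' Reads a plain `key = value` config file (or takes a named list), fills
#' defaults, and rejects unknown keys; all type and range errors are
#' reported together. A seed is mandatory whenever permutations are
#' requested (`n_perm > 0` with a `gmt` input).
#'
#' @param config path to a config file, or a named list.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    lines <- readLines(config)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", lines))
    bad <- lines[lengths(kv) != 3L]
    if (length(bad)) stop("unparseable config line(s): ", paste(bad, collapse = "; "))
    config <- stats::setNames(
      lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L)
    )
  }
  defaults <- list(
    genotypes = NULL, annotation = NULL, gmt = NULL, out_dir = "gwepi_out",
    p_screen = 1e-8, alpha = 0.05, maf_min = 0.05, hwe_p_min = 0.001,
    max_missing = 0.05, flank = 20000, n_perm = 1000, min_size = 5,
    max_size = 200, window_sizes = c(2, 3, 4), min_support = 2,
    haplotype_snps = NULL, seed = NULL, force = FALSE
  )
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) errs <- c(errs, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  num_keys <- c("p_screen", "alpha", "maf_min", "hwe_p_min", "max_missing",
                "flank", "n_perm", "min_size", "max_size", "min_support", "seed")
  out <- defaults
  for (k in intersect(names(config), names(defaults))) {
    v <- config[[k]]
    if (k %in% num_keys && is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (k == "window_sizes" && is.character(v)) {
      v <- suppressWarnings(as.numeric(strsplit(v, ",")[[1L]]))
    }
    if (k == "haplotype_snps" && is.character(v) && length(v) == 1L) {
      v <- strsplit(v, ",")[[1L]]
    }
    if (k == "force" && is.character(v)) v <- tolower(v) %in% c("true", "1", "yes")
    if (k %in% c(num_keys, "window_sizes") && anyNA(v)) {
      errs <- c(errs, paste0(k, ": not numeric"))
      next
    }
    out[[k]] <- v
  }
  if (is.null(out$genotypes)) errs <- c(errs, "genotypes: required")
  for (k in c("p_screen", "alpha")) {
    if (!is.null(out[[k]]) && (out[[k]] <= 0 || out[[k]] >= 1)) {
      errs <- c(errs, paste0(k, ": must be in (0, 1), got ", out[[k]]))
    }
  }
  for (k in c("maf_min", "hwe_p_min", "max_missing")) {
    if (!is.null(out[[k]]) && (out[[k]] < 0 || out[[k]] > 1)) {
      errs <- c(errs, paste0(k, ": must be in [0, 1], got ", out[[k]]))
    }
  }
  if (!all(out$window_sizes %in% 2:4)) errs <- c(errs, "window_sizes: each must be 2, 3 or 4")
  if (!is.null(out$gmt) && out$n_perm > 0 && is.null(out$seed)) {
    errs <- c(errs, "seed: required when permutations are requested")
  }
  if (length(errs)) stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  structure(out, class = "pipeline_config")
}

read_genotype_prefix <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) {
    read_plink_binary(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                      paste0(prefix, ".fam"))
  } else if (file.exists(paste0(prefix, ".ped"))) {
    read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  } else {
    stop("no .bed or .ped found for genotype prefix: ", prefix)
  }
}

#' Run the full analysis pipeline
#'
#' Executes QC, the pairwise epistasis scan with logistic refinement, locus
#' mapping, haplotype association over the top locus pair's SNPs, and
#' permutation GSEA, in that order, writing one TSV per stage plus a JSON
#' manifest (parameters, seed, per-stage row counts and wall time). Stages
#' whose output file already exists are skipped and their output re-read
#' unless `config$force` is set; the manifest records the reuse.
#'
#' @param config a validated `pipeline_config` (see [validate_config()]).
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "gwepi",
                   version = as.character(utils::packageVersion("gwepi")),
                   r_version = R.version.string,
                   parameters = config[!vapply(config, is.null, logical(1))],
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, file, rows, reused, t0) {
    manifest$stages[[name]] <<- list(
      file = file, rows = rows, reused = reused,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
    )
    message(sprintf("stage %-9s %s (%d rows%s)", name, file, rows,
                    if (reused) ", reused" else ""))
  }
  path <- function(f) file.path(config$out_dir, f)

  ## qc ------------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  qc_prefix <- path("qc_genotypes")
  reused <- file.exists(paste0(qc_prefix, ".bed")) && !config$force
  if (reused) {
    gm <- read_plink_binary(paste0(qc_prefix, ".bed"), paste0(qc_prefix, ".bim"),
                            paste0(qc_prefix, ".fam"))
  } else {
    gm <- read_genotype_prefix(config$genotypes)
    gm <- qc_filter(gm, qc_thresholds(config$maf_min, config$hwe_p_min,
                                      config$max_missing))
    write_plink_binary(gm, qc_prefix)
    write_variant_report(gm, path("qc_variants.tsv"))
  }
  stage("qc", path("qc_variants.tsv"), nrow(gm$variants), reused, t0)

  ## scan (screen + logistic refinement) ---------------------------------
  t0 <- proc.time()[["elapsed"]]
  scan_file <- path("scan.tsv")
  reused <- file.exists(scan_file) && !config$force
  if (reused) {
    scan <- utils::read.table(scan_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = c(snp1 = "character", chr1 = "character",
                                             snp2 = "character", chr2 = "character"))
    n_tests <- n_pairs(nrow(gm$variants))
  } else {
    scan <- pairwise_scan(gm, scan_config(
      p_screen = config$p_screen, alpha = config$alpha, min_maf = config$maf_min
    ))
    n_tests <- attr(scan, "n_tests")
    write_stage_tsv(scan, scan_file)
  }
  manifest$n_tests <- n_tests
  manifest$bonferroni <- bonferroni_threshold(config$alpha, n_tests)
  stage("scan", scan_file, nrow(scan), reused, t0)

  ## map (locus clustering) ----------------------------------------------
  pairs <- NULL
  if (!is.null(config$annotation)) {
    t0 <- proc.time()[["elapsed"]]
    map_file <- path("locus_pairs.tsv")
    reused <- file.exists(map_file) && !config$force
    if (reused) {
      pairs <- utils::read.table(map_file, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    } else {
      ann <- read_bed_annotation(config$annotation, flank_bp = 0)
      hits <- scan[scan$p_z < config$p_screen, , drop = FALSE]
      pairs <- apply_exclusion_criteria(
        hits, gm$variants[, c("snp_id", "chrom", "pos_bp")], ann,
        min_support = config$min_support
      )
      pairs$support <- NULL
      write_stage_tsv(pairs, map_file)
    }
    stage("map", map_file, nrow(pairs), reused, t0)
  }

  ## haplotype ------------------------------------------------------------
  hap_snps <- config$haplotype_snps
  if (is.null(hap_snps) && !is.null(pairs) && nrow(pairs)) {
    scr <- scan[scan$p_z < config$p_screen, , drop = FALSE]
    hap_snps <- intersect(gm$variants$snp_id, unique(c(scr$snp1, scr$snp2)))
  }
  if (!is.null(hap_snps) && length(hap_snps) >= 2L) {
    t0 <- proc.time()[["elapsed"]]
    hap_file <- path("haplotypes.tsv")
    reused <- file.exists(hap_file) && !config$force
    if (reused) {
      haps <- utils::read.table(hap_file, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    } else {
      haps <- haplotype_association_scan(gm, hap_snps,
                                         sizes = as.integer(config$window_sizes))
      write_stage_tsv(haps, hap_file)
    }
    stage("haplotype", hap_file, nrow(haps), reused, t0)
  }

  ## gsea ------------------------------------------------------------------
  if (!is.null(config$gmt) && !is.null(config$annotation) && config$n_perm > 0) {
    t0 <- proc.time()[["elapsed"]]
    gsea_file <- path("pathways.tsv")
    reused <- file.exists(gsea_file) && !config$force
    if (reused) {
      pw <- utils::read.table(gsea_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    } else {
      ann <- read_bed_annotation(config$annotation, flank_bp = config$flank)
      covered <- names(gene_snp_index(gm$variants, ann, config$flank))
      sets <- filter_gene_sets(read_gmt(config$gmt), covered,
                               min_size = config$min_size,
                               max_size = config$max_size)
      pw <- gsea_permutation_test(gm, ann, sets, n_perm = as.integer(config$n_perm),
                                  seed = as.integer(config$seed),
                                  flank = config$flank)
      write_stage_tsv(pw, gsea_file)
    }
    stage("gsea", gsea_file, nrow(pw), reused, t0)
  }

  manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
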