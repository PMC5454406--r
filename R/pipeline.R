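## known configuration schema: NULL marks "any value", lists nest
.config_schema <- function() list(
  seed = NULL,
  out_dir = NULL,
  inputs = list(fasta = NULL, intensity_tsvs = NULL, shape = NULL,
                alignment = NULL, alignment_format = NULL, manifest = NULL,
                reference_id = NULL, motifs = NULL, counts = NULL),
  normalization = list(sd_threshold = NULL),
  restraint = list(m = NULL, b = NULL, double_charge = NULL),
  model = list(path = NULL),
  fold = list(max_candidates = NULL),
  kissing = list(k = NULL, min_len = NULL, allow_wobble = NULL),
  conservation = list(focal_groups = NULL),
  retro = list(level = NULL, reference_strain = NULL))

#' Validate a pipeline configuration
#'
#' Checks every key (recursively) against the known schema; unknown keys
#' are rejected so typos fail loudly before any stage runs.
#'
#' @param config nested list, or path to a JSON config file
#' @return the validated config list, invisibly augmented with defaults
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  check <- function(cfg, schema, path = "") {
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(cfg)) {
      if (is.list(schema[[k]]) && !is.null(schema[[k]]))
        check(cfg[[k]], schema[[k]], paste0(path, k, "."))
    }
  }
  check(config, .config_schema())
  defaults <- list(seed = 1L, out_dir = "results",
                   normalization = list(sd_threshold = 0.7),
                   restraint = list(m = 1.8, b = -0.6, double_charge = TRUE),
                   fold = list(max_candidates = 20L),
                   kissing = list(k = 2L, min_len = 6L, allow_wobble = FALSE),
                   retro = list(level = 0.95))
  modifyList(defaults, config)
}

#' Hash a configuration for provenance stamps
#' @param config validated config list
#' @return md5 hex string of the canonical JSON serialization
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages the configuration provides inputs for:
#' intensity normalization (.shape + QC JSON), SHAPE-restrained pseudoknot
#' folding (CT, dot-bracket), structural annotation and pseudoknot core
#' extraction (BED, JSON), kissing-pair and palindrome scans (TSV),
#' conservation classification (TSV/BED) and retrotransposition statistics
#' (TSV). Every output carries the config hash and seed; rerunning with
#' the same config and inputs reproduces the report byte-for-byte.
#'
#' @param config nested list or JSON path; see [validate_config()]
#' @return list with the stage results and the path of the JSON report
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  set.seed(cfg$seed)
  model <- if (!is.null(cfg$model$path)) read_energy_model(cfg$model$path)
           else default_energy_model()
  params <- restraint_params(cfg$restraint$m, cfg$restraint$b,
                             cfg$restraint$double_charge)
  report <- list(config_hash = hash, seed = cfg$seed, stages = list())
  out <- list()
  pth <- function(f) file.path(cfg$out_dir, f)

  ## --- normalization
  profile <- NULL
  if (!is.null(cfg$inputs$intensity_tsvs)) {
    tabs <- lapply(cfg$inputs$intensity_tsvs, read_intensity_tsv)
    proc <- process_replicates(tabs, cfg$normalization$sd_threshold)
    profile <- reactivity_profile(proc$values,
                                  scale_factors = proc$scale_factors)
    write_shape(profile, pth("reactivity.shape"))
    write_qc_json(proc, pth("reactivity_qc.json"))
    report$stages$normalize <- list(
      scale_factors = proc$scale_factors,
      n_excluded = length(proc$excluded_positions))
    out$profile <- profile
  } else if (!is.null(cfg$inputs$shape)) {
    profile <- read_shape(cfg$inputs$shape)
    out$profile <- profile
  }

  ## --- folding + annotation + kissing
  if (!is.null(cfg$inputs$fasta)) {
    if (!file.exists(cfg$inputs$fasta))
      stop("input FASTA not found: ", cfg$inputs$fasta)
    ss <- Biostrings::readBStringSet(cfg$inputs$fasta)
    seq <- as.character(ss[[1L]])
    fold <- shapeknots_fold(seq, shape = profile, model = model,
                            params = params,
                            max_candidates = cfg$fold$max_candidates)
    write_ct(fold, seq, pth("structure.ct"),
             title = paste0("seed=", cfg$seed, " config=", hash))
    writeLines(c(paste0("> structure seed=", cfg$seed, " config=", hash),
                 chartr("tT", "uU", toupper(seq)), as_dotbracket(fold)),
               pth("structure.db"))
    core <- pseudoknot_core(fold)
    el <- enumerate_elements(fold)
    report$stages$fold <- list(
      energy = attr(fold, "energy"), n_pairs = n_pairs(fold),
      pseudoknotted = has_crossing(fold),
      core = if (!is.null(core)) list(
        S1_length = core$S1_length, S2_length = core$S2_length,
        L2 = core$L2_positions, span_3prime = core$span_3prime))
    if (nrow(el$stems))
      export_bed(data.frame(name = paste0("stem", seq_len(nrow(el$stems))),
                            start = el$stems$i5, end = el$stems$j3),
                 pth("stems.bed"))
    if (!is.null(cfg$inputs$motifs)) {
      mot <- annotate_motifs(cfg$inputs$motifs, nchar(seq))
      export_bed(mot, pth("motifs.bed"))
      report$stages$motifs <- nrow(mot)
    }
    kiss <- scan_kissing_pairs(fold, seq, k = cfg$kissing$k,
                               min_len = cfg$kissing$min_len,
                               allow_wobble = cfg$kissing$allow_wobble,
                               reactivity = profile)
    write.table(kiss, pth("kissing_candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pal <- palindrome_scan(seq)
    write.table(pal, pth("palindromes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$stages$kissing <- list(n_candidates = nrow(kiss),
                                  n_palindromes = nrow(pal))
    out$structure <- fold; out$core <- core; out$kissing <- kiss
  }

  ## --- conservation
  if (!is.null(cfg$inputs$alignment)) {
    aln <- read_grouped_alignment(
      cfg$inputs$alignment, cfg$inputs$manifest, cfg$inputs$reference_id,
      format = if (is.null(cfg$inputs$alignment_format)) "fasta"
               else cfg$inputs$alignment_format)
    track <- classify_conservation(aln, cfg$conservation$focal_groups)
    write_conservation_tsv(track, pth("conservation.tsv"))
    write_conservation_bed(track, pth("conservation.bed"))
    report$stages$conservation <-
      as.list(table(factor(track, levels = .conservation_levels)))
    out$conservation <- track
  }

  ## --- retrotransposition statistics
  if (!is.null(cfg$inputs$counts)) {
    counts <- read_culture_tsv(cfg$inputs$counts)
    summ <- summarize_strains(counts, cfg$retro$reference_strain,
                              cfg$retro$level)
    write.table(summ, pth("retro_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$stages$retro <- summ
    out$retro <- summ
  }

  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  out$report_path <- pth("report.json")
  out$report <- report
  invisible(out)
}
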