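# Pipeline orchestration and file formats: FASTA in/out, configuration
# handling, and a single entry point that chains motif scanning, effective
# concentrations, equilibrium constants and speciation, writing CSV/TSV/
# JSON reports. The exported functions are the package's interface; the
# pipeline is driven from R (or Rscript -e) rather than a bespoke shell
# tool.

#' Read and write protein FASTA
#'
#' Thin wrappers around `Biostrings` that move between files and named
#' character vectors; `read_alignment` additionally checks that all rows
#' have equal width.
#'
#' @param path FASTA file path.
#' @return `read_fasta`/`read_alignment` return a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: '%s'", path)
  as.character(Biostrings::readAAStringSet(path))
}

#' @rdname read_fasta
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  if (length(unique(nchar(seqs))) != 1L) {
    stopf("alignment rows in '%s' have unequal lengths", path)
  }
  seqs
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.default_config <- function() {
  list(
    classes = c("I", "II"),
    wlc = list(lp = 3.0, b = 3.8),
    temperature = 298,
    gas_constant = GAS_CONSTANT_KCAL,
    convention = "paper",
    substitutions = list(RP = "P3"),
    seed = 1L,
    fasta = NULL, msa = NULL,
    affinities = NULL,   # list(nsh3 =, csh3 =, ceff =) CSV paths
    motifs = NULL,       # subset of motif labels, e.g. c("P1","P2","P3")
    trace = NULL,        # list(path =, linker_n =) for a one-off C_eff
    speciation = NULL    # list(total_G =, total_S =, sweep = list(...))
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: '%s'", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stopf("'config' must be a list or a YAML/JSON path")
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, config)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full multivalent-binding pipeline
#'
#' Executes, as configured: motif scanning of input sequences (TSV
#' reports), alignment conservation (CSV), a one-off effective
#' concentration from a distance trace, assembly of the affinity model
#' (packaged reference tables unless CSV paths are supplied), the 1:1 and
#' 2:1 effective equilibrium constants, and the mass-action speciation.
#' All stochastic stages derive from the single configured seed, and every
#' report embeds the config hash and package version, so identical config
#' plus inputs give identical outputs.
#'
#' @param config A configuration list, or the path to a YAML/JSON file.
#'   Recognised keys (all optional): `fasta`, `classes`, `msa`,
#'   `affinities` (list with `nsh3`, `csh3`, `ceff` CSV paths), `motifs`
#'   (subset of motif labels), `trace` (list with `path`, `linker_n`),
#'   `wlc` (list with `lp`, `b`), `temperature`, `convention`
#'   (`"paper"`/`"strict"`), `substitutions`, `speciation` (list with
#'   `total_G`, `total_S` in molar and optional `sweep` with `vary`,
#'   `ratios`), `seed`.
#' @param out_dir Directory for the report files; created if needed. When
#'   `NULL`, nothing is written and results are only returned.
#' @return (Invisibly) a list with elements `motifs`, `layouts`,
#'   `conservation`, `ceff_trace`, `equilibrium`, `speciation`, `meta`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- .load_config(config)
  set.seed(cfg$seed)
  meta <- list(package_version = as.character(utils::packageVersion("avidity")),
               config_hash = .config_hash(cfg))
  results <- list(meta = meta)

  # --- sequence scanning -------------------------------------------------
  if (!is.null(cfg$fasta)) {
    seqs <- read_fasta(cfg$fasta)
    if (!length(seqs)) stopf("no sequences in '%s'", cfg$fasta)
    layouts <- lapply(names(seqs), function(id) {
      build_layout(id, scan_motifs(seqs[[id]], classes = cfg$classes))
    })
    names(layouts) <- names(seqs)
    motif_rows <- do.call(rbind, lapply(layouts, function(l) {
      if (!nrow(l$sites)) return(NULL)
      cbind(sequence_id = l$sequence_id, l$sites)
    }))
    linker_rows <- do.call(rbind, lapply(layouts, function(l) {
      if (length(l$linker_lengths) == 0L) return(NULL)
      data.frame(sequence_id = l$sequence_id,
                 site_pair = paste(l$sites$motif_id[-nrow(l$sites)],
                                   l$sites$motif_id[-1L], sep = "-"),
                 linker_aa = l$linker_lengths, stringsAsFactors = FALSE)
    }))
    results$motifs <- motif_rows
    results$linkers <- linker_rows
    results$layouts <- layouts
  }

  # --- alignment conservation -------------------------------------------
  if (!is.null(cfg$msa)) {
    prof <- column_conservation(read_alignment(cfg$msa))
    results$conservation <- data.frame(column = seq_len(prof$width),
                                       conservation = prof$conservation)
  }

  # --- one-off C_eff from a distance trace ------------------------------
  wlc <- wlc_params(lp = cfg$wlc$lp, b = cfg$wlc$b)
  if (!is.null(cfg$trace)) {
    if (is.null(cfg$trace$path) || is.null(cfg$trace$linker_n)) {
      stopf("'trace' config needs 'path' and 'linker_n'")
    }
    results$ceff_trace <- ceff_hybrid(cfg$trace$path,
                                      cfg$trace$linker_n, wlc)
  }

  # --- affinity model and effective equilibrium constants ---------------
  model <- if (is.null(cfg$affinities)) {
    sos1_affinity_model()
  } else {
    aff <- cfg$affinities
    nt <- utils::read.csv(aff$nsh3, stringsAsFactors = FALSE)
    ct <- utils::read.csv(aff$csh3, stringsAsFactors = FALSE)
    ce <- utils::read.csv(aff$ceff, stringsAsFactors = FALSE)
    affinity_model(stats::setNames(nt$kd_expt_uM, nt$motif),
                   stats::setNames(ct$kd_expt_uM, ct$motif),
                   ce[, c("n_motif", "c_motif", "ceff_mM")],
                   substitutions = unlist(cfg$substitutions),
                   temperature = cfg$temperature)
  }
  motifs <- if (is.null(cfg$motifs)) model$motifs else cfg$motifs
  if (!length(motifs)) stopf("empty motif list: nothing to analyse")
  gs <- k_gs(model, motifs)
  gsg <- if (length(motifs) >= 2L) k_gsg(model, motifs, cfg$convention)
         else NULL
  results$model <- model
  results$equilibrium <- list(
    motifs = motifs,
    n_modes = gs$n_modes,
    K_GS_per_uM = gs$K_GS, Kd_GS_uM = gs$Kd_GS,
    fraction_singly = gs$fraction_singly,
    fraction_doubly = gs$fraction_doubly,
    K_GSG_per_uM = if (is.null(gsg)) NA_real_ else gsg$K_GSG,
    Kd_GSG_uM = if (is.null(gsg)) NA_real_ else gsg$Kd_GSG,
    gsg_fractions = if (is.null(gsg)) NULL else as.list(gsg$gsg_fractions),
    convention = cfg$convention)

  # --- speciation --------------------------------------------------------
  if (!is.null(cfg$speciation)) {
    sp <- cfg$speciation
    K_GS_M <- gs$K_GS * 1e6       # uM^-1 -> M^-1
    K_GSG_M <- if (is.null(gsg)) 0 else gsg$K_GSG * 1e6
    results$speciation <- solve_equilibrium(sp$total_G, sp$total_S,
                                            K_GS_M, K_GSG_M)
    if (!is.null(sp$sweep)) {
      results$sweep <- stoichiometry_sweep(sp$total_G, sp$total_S,
                                           K_GS_M, K_GSG_M,
                                           vary = sp$sweep$vary,
                                           ratios = sp$sweep$ratios)
    }
  }

  # --- reports -----------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(df) df  # tabular reports carry meta in results.json
    if (!is.null(results$motifs)) {
      utils::write.table(stamp(results$motifs),
                         file.path(out_dir, "motifs.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(results$linkers)) {
      utils::write.table(stamp(results$linkers),
                         file.path(out_dir, "linkers.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(results$conservation)) {
      utils::write.csv(results$conservation,
                       file.path(out_dir, "conservation.csv"),
                       row.names = FALSE)
    }
    if (!is.null(results$sweep)) {
      utils::write.csv(results$sweep, file.path(out_dir, "speciation_sweep.csv"),
                       row.names = FALSE)
    }
    summary_json <- list(
      meta = meta,
      equilibrium = results$equilibrium,
      ceff_trace_mM = if (is.null(results$ceff_trace)) NULL
                      else results$ceff_trace$value_mM,
      speciation = if (is.null(results$speciation)) NULL else
        results$speciation[c("free_G", "free_S", "conc_GS", "conc_GSG",
                             "f_GSG", "effective_stoichiometry")])
    jsonlite::write_json(summary_json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(results)
}
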