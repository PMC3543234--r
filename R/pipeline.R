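#' Full-analysis configuration
#'
#' Bundles inputs and settings for [run_full_analysis()].  Defaults follow
#' the package-wide conventions: 10,000 permutations for every permutation
#' test and a 10 km cap on pair distances in the spatial analysis.
#'
#' @param genotypes a [genotype_data] object or path to a genotype CSV.
#' @param haplotypes optional [haplotype_data] object or path to a haplotype
#'   CSV.
#' @param out_dir output directory (created if absent).
#' @param by grouping column for population-level statistics.
#' @param permutations permutation count for all tests (default 10,000).
#' @param max_distance SGS pair-distance cap in meters (default 10,000).
#' @param sgs_min_n minimum individuals for a per-population SGS run
#'   (default 50).
#' @param min_pairs,nn_fraction distance-class settings, see
#'   [make_distance_classes()].
#' @param seed RNG seed recorded in every output file.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(genotypes, haplotypes = NULL, out_dir = ".",
                            by = "pop", permutations = 10000,
                            max_distance = 10000, sgs_min_n = 50,
                            min_pairs = 100, nn_fraction = 0.9, seed = 42) {
  structure(list(genotypes = genotypes, haplotypes = haplotypes,
                 out_dir = out_dir, by = by, permutations = permutations,
                 max_distance = max_distance, sgs_min_n = sgs_min_n,
                 min_pairs = min_pairs, nn_fraction = nn_fraction,
                 seed = seed),
            class = "analysis_config")
}

config_metadata <- function(config) {
  checksums <- list()
  for (f in c("genotypes", "haplotypes")) {
    v <- config[[f]]
    if (is.character(v) && length(v) == 1 && file.exists(v))
      checksums[[f]] <- unname(tools::md5sum(v))
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  hashed <- config[setdiff(names(config), "out_dir")]  # where, not what
  scalars <- hashed[vapply(hashed, function(v) is.numeric(v) || is.character(v),
                           logical(1))]
  writeLines(paste(names(scalars), vapply(scalars, paste, character(1),
                                          collapse = ","), sep = "="), tmp)
  list(package_version = as.character(utils::packageVersion("pollenseed")),
       rng_seed = config$seed,
       config_hash = unname(tools::md5sum(tmp)),
       input_checksums = checksums)
}

write_result_json <- function(x, path, meta) {
  jsonlite::write_json(c(list(metadata = meta), x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pollen-versus-seed analysis pipeline
#'
#' Executes, in order: per-population diversity, multilocus Weir-Cockerham
#' F-statistics, pairwise F_ST with permutation tests, AMOVA on the nuclear
#' and (when available) organelle data, per-population spatial genetic
#' structure, and the pollen-versus-seed gene-flow comparison.  Each stage
#' writes a TSV and/or JSON table analogue into `out_dir`; every JSON embeds
#' the package version, a configuration hash, the RNG seed and input
#' checksums, and the run is deterministic given the seed.  A failing stage
#' aborts with a stage-labeled error; outputs of completed stages remain on
#' disk.
#'
#' @param config an [analysis_config()].
#' @return Invisibly, a named list with every stage result (`diversity`,
#'   `fstats`, `pairwise`, `amova_nuclear`, `amova_organelle`, `sgs`,
#'   `geneflow`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- config_metadata(config)
  g <- config$genotypes
  if (is.character(g)) g <- read_genotype_table(g, dialect = "csv")
  h <- config$haplotypes
  if (is.character(h) && !is.null(h)) h <- read_haplotype_table(h)
  set.seed(config$seed)
  bundle <- list()
  stage <- function(name, expr) {
    message("[pollenseed] stage: ", name, " (", length(g$ind),
            " individuals, ", length(g$loci), " loci)")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- file.path(config$out_dir, c(
    diversity = "diversity.tsv", fstats = "fstats.json",
    fstats_tsv = "fstats_per_locus.tsv", pairwise = "pairwise_fst.tsv",
    amova_nuc = "amova_nuclear.json", amova_org = "amova_organelle.json",
    geneflow = "geneflow.json", combined = "combined.json"))
  names(out) <- c("diversity", "fstats", "fstats_tsv", "pairwise",
                  "amova_nuc", "amova_org", "geneflow", "combined")

  bundle$diversity <- stage("diversity", summary_diversity(g))
  write_tsv(bundle$diversity, out["diversity"])

  bundle$fstats <- stage("fstats", wc_f_statistics(g, by = config$by))
  write_result_json(unclass(bundle$fstats)[c("F_ST", "F_IS", "SE_FST",
                                             "SE_FIS", "t")],
                    out["fstats"], meta)
  write_tsv(bundle$fstats$per_locus, out["fstats_tsv"])

  bundle$pairwise <- stage("pairwise_fst",
                           pairwise_fst(g, n_perm = config$permutations))
  pw <- as.data.frame(as.table(bundle$pairwise$fst))
  names(pw) <- c("pop1", "pop2", "fst")
  pw$p <- as.data.frame(as.table(bundle$pairwise$p))$Freq
  pw <- pw[as.integer(pw$pop1) < as.integer(pw$pop2), ]
  write_tsv(pw, out["pairwise"])

  bundle$amova_nuclear <- stage("amova_nuclear",
                                amova_nuclear(g, by = config$by,
                                              n_perm = config$permutations))
  write_result_json(unclass(bundle$amova_nuclear), out["amova_nuc"], meta)

  if (!is.null(h)) {
    bundle$amova_organelle <- stage("amova_organelle",
                                    amova_haplotype(h, n_perm = config$permutations))
    write_result_json(unclass(bundle$amova_organelle), out["amova_org"], meta)
  }

  bundle$sgs <- list()
  if (!is.null(g$coords)) {
    for (p in unique(g$pop)) {
      idx <- which(g$pop == p)
      if (length(idx) < config$sgs_min_n) next
      sub <- gd_subset(g, idx)
      res <- stage(paste0("sgs:", p), tryCatch({
        kin <- loiselle_kinship(sub)
        dm <- pairwise_geographic_distance(sub)
        kinship_distance_regression(kin, dm, n_perm = config$permutations,
                                    max_distance = config$max_distance,
                                    min_pairs = config$min_pairs,
                                    nn_fraction = config$nn_fraction)
      }, error = function(e) e))
      if (inherits(res, "error")) {
        message("[pollenseed] sgs skipped for ", p, ": ", conditionMessage(res))
        next
      }
      bundle$sgs[[p]] <- res
      curve <- data.frame(class_edge = res$class_edges,
                          mean_distance = res$class_mean_distance,
                          mean_kinship = res$class_mean_kinship,
                          n_pairs = res$class_n_pairs)
      write_tsv(curve, file.path(config$out_dir, paste0("sgs_curve_", p, ".tsv")))
      write_result_json(unclass(res)[c("b_ld", "R2_ld", "SE_b", "p_perm",
                                       "F_A", "Sp", "n_perm", "max_distance",
                                       "n_zero_dropped")],
                        file.path(config$out_dir, paste0("sgs_", p, ".json")),
                        meta)
    }
  }

  if (!is.null(h)) {
    bundle$geneflow <- stage("geneflow", gene_flow_analysis(g, h, by = config$by))
    gf <- unclass(bundle$geneflow)
    attributes(gf) <- NULL
    names(gf) <- names(unclass(bundle$geneflow))
    write_result_json(gf, out["geneflow"], meta)
    bundle$haplotype_diversity <- stage("haplotype_diversity",
                                        haplotype_diversity(h))
    write_tsv(bundle$haplotype_diversity,
              file.path(config$out_dir, "haplotype_diversity.tsv"))
  }

  combined <- list(
    fstats = unclass(bundle$fstats)[c("F_ST", "F_IS", "SE_FST", "SE_FIS", "t")],
    amova_nuclear = unclass(bundle$amova_nuclear),
    amova_organelle = if (!is.null(h)) unclass(bundle$amova_organelle),
    sgs = lapply(bundle$sgs, function(r)
      unclass(r)[c("b_ld", "R2_ld", "SE_b", "p_perm", "F_A", "Sp")]),
    geneflow = if (!is.null(h)) {
      gf <- unclass(bundle$geneflow); attributes(gf) <- NULL
      names(gf) <- names(unclass(bundle$geneflow)); gf
    })
  write_result_json(combined[!vapply(combined, is.null, logical(1))],
                    out["combined"], meta)
  invisible(bundle)
}

#' Read a YAML configuration
#'
#' Reads either an analysis configuration (fields of [analysis_config()]) or
#' a simulation configuration (fields of [sim_config()]), depending on
#' `type`; unknown fields are rejected.
#'
#' @param path YAML file.
#' @param type `"analysis"` or `"simulation"`.
#' @return An `analysis_config` or `sim_config`.
#' @export
read_config_yaml <- function(path, type = c("analysis", "simulation")) {
  type <- match.arg(type)
  # keep bare YAML-1.1 boolean-like scalars (N, y, no, ...) as literal
  # strings so a key like "N" survives; no config field is a boolean
  keep <- function(x) x
  vals <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = keep, "bool#no" = keep))
  fun <- if (type == "analysis") analysis_config else sim_config
  known <- names(formals(fun))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(fun, vals)
}
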