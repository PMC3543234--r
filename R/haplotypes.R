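#' Organelle haplotype dataset
#'
#' Haploid, maternally inherited marker data: one haplotype identifier per
#' individual, a population label, and a haplotype-by-haplotype matrix of
#' mutational differences (number of differing aligned sites).
#'
#' @param ind character vector of unique individual identifiers.
#' @param pop character vector of population labels.
#' @param haplotype integer haplotype identifiers (one per individual).
#' @param dist optional haplotype x haplotype distance matrix (non-negative
#'   integers, zero diagonal, symmetric), with dimnames giving the haplotype
#'   identifiers.  When omitted, unit distances (1 between any two distinct
#'   haplotypes) are assumed.
#' @return An object of class `haplotype_data`.
#' @export
haplotype_data <- function(ind, pop, haplotype, dist = NULL) {
  ind <- as.character(ind); pop <- as.character(pop)
  haplotype <- as.integer(haplotype)
  n <- length(ind)
  if (anyDuplicated(ind)) stop("duplicate individual_id")
  if (length(pop) != n || length(haplotype) != n || anyNA(haplotype))
    stop("ind, pop and haplotype must be aligned and complete")
  haps <- sort(unique(haplotype))
  if (is.null(dist)) {
    dist <- 1 - diag(length(haps))
    dimnames(dist) <- list(haps, haps)
  }
  dist <- as.matrix(dist)
  if (is.null(rownames(dist))) dimnames(dist) <- list(haps, haps)
  if (!all(as.character(haps) %in% rownames(dist)))
    stop("every haplotype_id must be present in the distance matrix")
  if (!isSymmetric(unname(dist)) || any(diag(dist) != 0) || any(dist < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  structure(list(ind = ind, pop = pop, haplotype = haplotype, dist = dist),
            class = "haplotype_data")
}

#' @export
print.haplotype_data <- function(x, ...) {
  cat("haplotype_data:", length(x$ind), "individuals,",
      length(unique(x$haplotype)), "haplotypes,",
      length(unique(x$pop)), "populations\n")
  invisible(x)
}

#' Read a haplotype table
#'
#' Reads a CSV with columns `id,pop,haplotype`; an optional distance matrix
#' (CSV with haplotype ids as header and row names) supplies the mutational
#' steps between haplotypes, otherwise unit distances are assumed.
#'
#' @param path haplotype assignment CSV.
#' @param distances optional path to a distance-matrix CSV.
#' @return A [haplotype_data] object.
#' @export
read_haplotype_table <- function(path, distances = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "pop", "haplotype") %in% names(df)))
    stop("haplotype table needs 'id', 'pop', 'haplotype' columns")
  d <- NULL
  if (!is.null(distances)) {
    d <- as.matrix(utils::read.csv(distances, row.names = 1, check.names = FALSE))
    colnames(d) <- sub("^X", "", colnames(d))
  }
  haplotype_data(df$id, df$pop, df$haplotype, dist = d)
}

#' Write a haplotype table
#'
#' @param x a [haplotype_data] object.
#' @param path output CSV (`id,pop,haplotype`).
#' @param distances optional path for the distance-matrix CSV.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path, distances = NULL) {
  utils::write.csv(data.frame(id = x$ind, pop = x$pop, haplotype = x$haplotype),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(distances))
    utils::write.csv(as.data.frame(x$dist), distances, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Collapse an alignment into haplotypes
#'
#' Reduces pre-aligned organelle sequences to haplotype classes.  Alignment
#' columns containing any gap or non-ACGT symbol in any sequence are removed
#' globally (complete-column deletion), so the resulting pairwise differences
#' form a true Hamming metric on the retained columns.  Identical retained
#' strings share a haplotype id, numbered by first occurrence in the input.
#'
#' @param fasta path to an aligned FASTA file, or a character matrix
#'   (sequences x sites) with rownames as sequence ids.
#' @param pop_map data frame with columns `id` and `pop` mapping sequence ids
#'   to population labels.
#' @param ambiguity_policy only `"drop_columns"` is implemented.
#' @return A [haplotype_data] object whose distance matrix counts differing
#'   retained sites between haplotypes.
#' @export
collapse_fasta_to_haplotypes <- function(fasta, pop_map,
                                         ambiguity_policy = "drop_columns") {
  ambiguity_policy <- match.arg(ambiguity_policy, "drop_columns")
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- ape::read.FASTA(fasta)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L)
      stop("sequences are not aligned: unequal lengths")
    m <- toupper(do.call(rbind, as.character(seqs)))
    rownames(m) <- names(seqs)
  } else {
    m <- toupper(as.matrix(fasta))
    if (is.null(rownames(m))) stop("sequence matrix needs rownames (ids)")
  }
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("empty alignment after ambiguous-column removal")
  key <- apply(m, 1, paste0, collapse = "")
  hap_of <- match(key, unique(key))          # id by first occurrence
  reps <- m[match(unique(key), key), , drop = FALSE]
  k <- nrow(reps)
  d <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- sum(reps[i, ] != reps[j, ])
  ids <- rownames(m)
  pops <- pop_map$pop[match(ids, pop_map$id)]
  if (anyNA(pops)) stop("pop_map is missing ids: ",
                        paste(ids[is.na(pops)], collapse = ", "))
  haplotype_data(ids, pops, hap_of, dist = d)
}

#' Pairwise geographic distances in meters
#'
#' Great-circle (haversine, sphere radius 6,371,000 m) distances for
#' coordinates in decimal degrees; Euclidean distances for planar meter
#' coordinates.
#'
#' @param coords individuals x 2 matrix: (lat, lon) for degrees, (x, y) for
#'   meters.  A [genotype_data] object may be passed directly.
#' @param units `"degrees"` or `"meters"` (taken from the dataset when a
#'   [genotype_data] object is supplied).
#' @return Symmetric individuals x individuals matrix of distances in meters.
#' @export
pairwise_geographic_distance <- function(coords, units = c("degrees", "meters")) {
  if (inherits(coords, "genotype_data")) {
    x <- coords
    if (is.null(x$coords)) stop("dataset has no coordinates")
    units <- x$coord_units
    coords <- x$coords
  } else {
    units <- match.arg(units)
  }
  coords <- as.matrix(coords)
  if (anyNA(coords)) stop("missing coordinates for an individual")
  n <- nrow(coords)
  if (units == "meters") {
    d <- as.matrix(stats::dist(coords))
  } else {
    lonlat <- coords[, 2:1, drop = FALSE]    # geosphere wants (lon, lat)
    d <- matrix(0, n, n)
    for (i in seq_len(n))
      d[i, ] <- geosphere::distHaversine(lonlat[i, ], lonlat, r = 6371000)
  }
  dimnames(d) <- NULL
  d
}
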