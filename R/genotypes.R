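#' Diploid genotype dataset
#'
#' Container for individuals typed at co-dominant diploid loci (microsatellite
#' allele labels are positive integers, typically repeat sizes), with a
#' population label per individual, an optional subpopulation (deme/transect)
#' label, and optional geographic coordinates.
#'
#' A genotype at a locus is either fully present (two alleles) or fully
#' missing: half-calls are rejected rather than imputed, matching standard
#' microsatellite scoring practice.
#'
#' @param ind character vector of unique individual identifiers.
#' @param pop character vector of population labels (one per individual).
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   labels per locus; `NA` in both marks a missing genotype.
#' @param subpop optional character vector of subpopulation labels.
#' @param coords optional numeric matrix (individuals x 2); interpreted
#'   according to `coord_units`: `"degrees"` columns are (lat, lon),
#'   `"meters"` columns are planar (x, y).
#' @param coord_units `"degrees"`, `"meters"`, or `NA` when no coordinates.
#' @param loci optional character vector of locus names (defaults to the
#'   column names of `a1`).
#'
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(ind, pop, a1, a2, subpop = NULL, coords = NULL,
                          coord_units = NA_character_, loci = NULL) {
  ind <- as.character(ind)
  pop <- as.character(pop)
  n <- length(ind)
  if (anyDuplicated(ind))
    stop("duplicate individual_id: ", paste(unique(ind[duplicated(ind)]), collapse = ", "))
  if (length(pop) != n || anyNA(pop))
    stop("every individual needs a population label")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (nrow(a1) != n || !identical(dim(a1), dim(a2)))
    stop("allele matrices must be individuals x loci and conformable")
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(a1)))
  colnames(a1) <- colnames(a2) <- loci
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype (one allele of two) for individual '",
         ind[w[1]], "' at locus '", loci[w[2]], "'")
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele labels must be positive integers")
  if (!is.null(subpop)) {
    subpop <- as.character(subpop)
    if (length(subpop) != n) stop("subpop length mismatch")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2)
      stop("coords must be an individuals x 2 matrix")
    if (!coord_units %in% c("degrees", "meters"))
      stop("coord_units must be 'degrees' or 'meters' when coords are given")
  } else {
    coord_units <- NA_character_
  }
  structure(list(ind = ind, pop = pop, subpop = subpop, coords = coords,
                 coord_units = coord_units, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", length(x$ind), "individuals,", length(x$loci),
      "loci,", length(unique(x$pop)), "populations\n")
  cat("  populations:", paste(utils::head(unique(x$pop), 8), collapse = ", "), "\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%; coordinates: %s\n", 100 * miss,
              if (is.null(x$coords)) "none" else x$coord_units))
  invisible(x)
}

# subset by individual index, keeping all metadata aligned
gd_subset <- function(x, idx) {
  genotype_data(x$ind[idx], x$pop[idx], x$a1[idx, , drop = FALSE],
                x$a2[idx, , drop = FALSE],
                subpop = if (!is.null(x$subpop)) x$subpop[idx],
                coords = if (!is.null(x$coords)) x$coords[idx, , drop = FALSE],
                coord_units = x$coord_units, loci = x$loci)
}

#' Read a genotype table
#'
#' Reads diploid genotypes from either the canonical CSV layout
#' (`id,pop[,subpop][,lat,lon|,x,y],<locus>_1,<locus>_2,...`) or a GENEPOP
#' file (2- or 3-digit allele encoding, `0`-padded zeros meaning missing,
#' `POP` separators delimiting populations).
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"genepop"`.
#' @return A [genotype_data] object.  GENEPOP input carries no coordinates or
#'   subpopulations; its POP blocks become populations `pop_1`, `pop_2`, ...
#' @export
read_genotype_table <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect, csv = read_genotype_csv(path), genepop = read_genepop(path))
}

parse_allele_column <- function(v, col, offset = 1L) {
  v <- as.character(v)
  v[!nzchar(trimws(v))] <- NA_character_
  out <- suppressWarnings(as.integer(v))
  bad <- which(!is.na(v) & is.na(out) & toupper(trimws(v)) != "NA")
  if (length(bad))
    stop("unparseable allele token '", v[bad[1]], "' in column '", col,
         "' at line ", bad[1] + offset)
  out[toupper(trimws(v)) %in% "NA"] <- NA_integer_
  out
}

read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("id", "pop") %in% names(df)))
    stop("CSV genotype table needs 'id' and 'pop' columns")
  meta <- c("id", "pop", "subpop", "lat", "lon", "x", "y")
  allele_cols <- setdiff(names(df), meta)
  if (length(allele_cols) %% 2L != 0L)
    stop("format error: odd number of allele columns (", length(allele_cols), ")")
  base <- sub("_[12]$", "", allele_cols)
  loci <- unique(base)
  for (l in loci) {
    if (!all(paste0(l, c("_1", "_2")) %in% allele_cols))
      stop("format error: locus '", l, "' lacks a <locus>_1/<locus>_2 column pair")
  }
  a1 <- sapply(loci, function(l) parse_allele_column(df[[paste0(l, "_1")]], paste0(l, "_1")))
  a2 <- sapply(loci, function(l) parse_allele_column(df[[paste0(l, "_2")]], paste0(l, "_2")))
  if (nrow(df) == 1L) { a1 <- matrix(a1, 1); a2 <- matrix(a2, 1) }
  colnames(a1) <- colnames(a2) <- loci
  coords <- NULL; units <- NA_character_
  if (all(c("lat", "lon") %in% names(df))) {
    coords <- cbind(as.numeric(df$lat), as.numeric(df$lon)); units <- "degrees"
  } else if (all(c("x", "y") %in% names(df))) {
    coords <- cbind(as.numeric(df$x), as.numeric(df$y)); units <- "meters"
  }
  genotype_data(df$id, df$pop, a1, a2,
                subpop = if ("subpop" %in% names(df)) df$subpop,
                coords = coords, coord_units = units, loci = loci)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("format error: truncated GENEPOP file")
  body <- lines[-1]                        # first line is a title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("format error: no POP separator")
  locus_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ind <- character(); pop <- character()
  rows1 <- list(); rows2 <- list()
  pop_i <- 0L
  for (k in seq(first_pop, length(body))) {
    line <- body[k]
    if (toupper(trimws(line)) == "POP") { pop_i <- pop_i + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2)
      stop("format error: expected 'id , alleles' at line ", k + 1L)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[[:space:]]+")[[1]]
    if (length(toks) != length(loci))
      stop("format error: ", length(toks), " genotype tokens for ",
           length(loci), " loci at line ", k + 1L)
    g <- vapply(seq_along(toks), function(j) {
      tok <- toks[j]
      w <- nchar(tok) / 2L
      if (!nchar(tok) %in% c(4L, 6L) || grepl("[^0-9]", tok))
        stop("unparseable allele token '", tok, "' at line ", k + 1L)
      al <- c(as.integer(substr(tok, 1L, w)), as.integer(substr(tok, w + 1L, 2L * w)))
      if (xor(al[1] == 0L, al[2] == 0L))
        stop("half-missing genotype token '", tok, "' at line ", k + 1L)
      al
    }, integer(2))
    ind <- c(ind, id); pop <- c(pop, paste0("pop_", pop_i))
    rows1[[length(rows1) + 1L]] <- g[1, ]
    rows2[[length(rows2) + 1L]] <- g[2, ]
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  colnames(a1) <- colnames(a2) <- loci
  genotype_data(ind, pop, a1, a2, loci = loci)
}

#' Write a genotype table
#'
#' Serializes a [genotype_data] object to the canonical CSV layout or to
#' GENEPOP.  GENEPOP output drops coordinates and subpopulation labels (the
#' format has no place for them) and uses 3-digit allele encoding whenever an
#' allele label exceeds 99.
#'
#' @param x a [genotype_data] object.
#' @param path output file.
#' @param dialect `"csv"` or `"genepop"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(id = x$ind, pop = x$pop, stringsAsFactors = FALSE)
    if (!is.null(x$subpop)) df$subpop <- x$subpop
    if (!is.null(x$coords)) {
      if (x$coord_units == "degrees") { df$lat <- x$coords[, 1]; df$lon <- x$coords[, 2] }
      else { df$x <- x$coords[, 1]; df$y <- x$coords[, 2] }
    }
    for (l in x$loci) {
      df[[paste0(l, "_1")]] <- x$a1[, l]
      df[[paste0(l, "_2")]] <- x$a2[, l]
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    mx <- max(c(x$a1, x$a2), na.rm = TRUE)
    w <- if (mx > 99) 3L else 2L
    if (mx >= 10^w) stop("allele label ", mx, " does not fit GENEPOP ", w, "-digit encoding")
    fmt <- function(m) {
      m[is.na(m)] <- 0L
      matrix(formatC(m, width = w, flag = "0"), nrow = nrow(m))
    }
    s1 <- fmt(x$a1); s2 <- fmt(x$a2)
    out <- c("pollenseed genotype export", x$loci)
    for (p in unique(x$pop)) {
      out <- c(out, "POP")
      idx <- which(x$pop == p)
      out <- c(out, vapply(idx, function(i)
        paste0(x$ind[i], " ,  ", paste0(s1[i, ], s2[i, ], collapse = " ")),
        character(1)))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Allele frequency table
#'
#' Relative allele frequencies per population and locus, computed from
#' non-missing genotypes (each typed individual contributes two gene copies).
#'
#' @param x a [genotype_data] object.
#' @param by `"pop"` for per-population tables or `"all"` for the pooled sample.
#' @return A data frame with columns `pop`, `locus`, `allele`, `freq`,
#'   `n_copies` (gene copies typed in that population x locus cell).
#'   Frequencies sum to 1 within each cell with `n_copies > 0`.
#' @export
allele_frequencies <- function(x, by = c("pop", "all")) {
  by <- match.arg(by)
  pops <- if (by == "pop") x$pop else rep("all", length(x$ind))
  res <- list()
  for (l in x$loci) {
    al <- c(x$a1[, l], x$a2[, l])
    pp <- factor(rep(pops, 2))
    keep <- !is.na(al)
    if (!any(keep)) next
    tab <- table(pp[keep], al[keep])
    for (p in rownames(tab)) {
      cnt <- tab[p, ]
      n <- sum(cnt)
      if (n == 0) next
      nz <- cnt > 0
      res[[length(res) + 1L]] <- data.frame(
        pop = p, locus = l, allele = as.integer(colnames(tab)[nz]),
        freq = as.numeric(cnt[nz]) / n, n_copies = n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
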