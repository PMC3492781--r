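## GENEPOP genotype files and labeled delimited matrices.

#' Read a GENEPOP file into a GenotypePanel
#'
#' Parses the standard format: a title line, locus names (one per line or a
#' single comma-separated line), and `Pop` blocks of individual lines
#' `"id ... , code code ..."` with 2- or 3-digit allele codes. The site
#' label of an individual is the last whitespace-separated token before the
#' comma. `00`/`000` allele codes mark missing data; a genotype with either
#' copy missing is treated as wholly missing.
#'
#' @param path file path.
#' @return A [GenotypePanel-class] (clusters initialised to sites).
#' @export
readGenepop <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("not a GENEPOP file: too few lines")
  body <- lines[-1L]
  isPop <- tolower(trimws(body)) == "pop"
  firstPop <- which(isPop)[1L]
  if (is.na(firstPop)) stop("no 'Pop' line found")
  if (firstPop == 1L) stop("no locus names before first Pop")
  locLines <- trimws(body[seq_len(firstPop - 1L)])
  loci <- if (length(locLines) == 1L && grepl(",", locLines)) {
    trimws(strsplit(locLines, ",")[[1L]])
  } else {
    locLines
  }
  L <- length(loci)
  a1 <- list()
  a2 <- list()
  ids <- character(0)
  siteLab <- character(0)
  popStarts <- which(isPop)
  popEnds <- c(popStarts[-1L] - 1L, length(body))
  for (p in seq_along(popStarts)) {
    rows <- body[seq(popStarts[p] + 1L, length.out = popEnds[p] - popStarts[p])]
    if (!length(rows)) stop("empty Pop block #", p)
    for (r in seq_along(rows)) {
      lineNo <- 1L + popStarts[p] + r # position in the file
      parts <- strsplit(rows[r], ",")[[1L]]
      if (length(parts) < 2L) {
        stop("line ", lineNo, ": expected 'id , genotypes'")
      }
      idPart <- trimws(parts[1L])
      idTokens <- strsplit(idPart, "\\s+")[[1L]]
      codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
      if (length(codes) != L) {
        stop(
          "line ", lineNo, ": ", length(codes), " genotype(s), expected ",
          L, " loci"
        )
      }
      widths <- unique(nchar(codes))
      if (length(widths) != 1L || !widths %in% c(4L, 6L)) {
        stop("line ", lineNo, ": allele codes must be uniformly 2 or 3 digits")
      }
      d <- widths / 2L
      x <- as.integer(substr(codes, 1L, d))
      y <- as.integer(substr(codes, d + 1L, 2L * d))
      if (anyNA(x) || anyNA(y)) {
        stop("line ", lineNo, ": non-numeric allele code")
      }
      miss <- x == 0L | y == 0L
      x[miss] <- NA_integer_
      y[miss] <- NA_integer_
      a1[[length(a1) + 1L]] <- x
      a2[[length(a2) + 1L]] <- y
      ids <- c(ids, idPart)
      siteLab <- c(siteLab, idTokens[length(idTokens)])
    }
  }
  A <- do.call(rbind, a1)
  B <- do.call(rbind, a2)
  colnames(A) <- loci
  rownames(A) <- make.unique(ids)
  colnames(B) <- loci
  GenotypePanel(A, B, site = siteLab)
}

#' Write a GenotypePanel as GENEPOP
#'
#' One `Pop` block per site, 3-digit allele codes, `000000` for missing
#' genotypes. Individual lines are `"id site , codes"` so the site label
#' survives a round trip as the last token before the comma.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output file path.
#' @param title title line content.
#' @return The path, invisibly.
#' @export
writeGenepop <- function(panel, path, title = "vecgen genotype panel") {
  if (any(panel@alleleA > 999L, na.rm = TRUE)) {
    stop("allele sizes exceed 3-digit GENEPOP coding")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(locNames(panel), con)
  fmt <- function(a, b) {
    out <- sprintf("%03d%03d", a, b)
    out[is.na(a)] <- "000000"
    out
  }
  for (s in unique(sites(panel))) {
    writeLines("Pop", con)
    for (i in which(sites(panel) == s)) {
      writeLines(paste0(
        indNames(panel)[i], " ", s, " ,  ",
        paste(fmt(panel@alleleA[i, ], panel@alleleB[i, ]), collapse = " ")
      ), con)
    }
  }
  invisible(path)
}

#' Read / write a labeled square matrix as delimited text
#'
#' Tab-separated, first row and first column carry the labels.
#'
#' @param m labeled square numeric matrix.
#' @param path file path.
#' @return `readLabeledMatrix` returns the matrix; `writeLabeledMatrix` the
#'   path, invisibly.
#' @export
writeLabeledMatrix <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname writeLabeledMatrix
#' @export
readLabeledMatrix <- function(path) {
  x <- read.table(path,
    sep = "\t", header = TRUE, row.names = 1L,
    check.names = FALSE
  )
  as.matrix(x)
}
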