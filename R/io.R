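#' @include AllClasses.R
NULL

## Readers validate and reject malformed input; every writer produces files
## its paired reader accepts bit-exactly (tab separator, UTF-8, no quoting,
## '.' decimal).

#' Read / write an expression matrix as TSV
#'
#' The file has a header row of sample ids, a first column of gene ids and
#' one numeric column per sample.  Values are written with full precision so
#' that `readExpressionTsv(writeExpressionTsv(m))` reproduces `m` exactly.
#'
#' @param path File path.
#' @return `readExpressionTsv`: a numeric matrix with gene row names and
#'   sample column names.
#' @export
readExpressionTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE)
  genes <- dt[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  samples <- colnames(dt)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  for (j in seq_along(samples)) {
    col <- dt[[j + 1L]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad], genes[bad], samples[j]), call. = FALSE)
    }
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  dimnames(m) <- list(genes, samples)
  if (!all(is.finite(m))) stop("expression values must be finite",
                               call. = FALSE)
  m
}

#' @rdname readExpressionTsv
#' @param x Numeric matrix (genes x samples) or [FractionExperiment-class].
#' @param idColumn Name of the gene-id column in the written file.
#' @export
writeExpressionTsv <- function(x, path, idColumn = "gene") {
  if (is(x, "FractionExperiment")) x <- assay(x, "exprs")
  stopifnot(is.matrix(x))
  ## %.17g guarantees bit-exact doubles on re-read
  chr <- matrix(sprintf("%.17g", x), nrow(x))
  dt <- data.table::as.data.table(chr)
  data.table::setnames(dt, colnames(x))
  dt <- cbind(data.table::data.table(.id = rownames(x)), dt)
  data.table::setnames(dt, ".id", idColumn)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write sample annotation as TSV
#'
#' @param path File path.
#' @param ann data.frame of per-sample annotation with a `sample` column.
#' @return `readSampleAnnotation`: data.frame.
#' @export
readSampleAnnotation <- function(path) {
  ann <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!"sample" %in% names(ann))
    stop("annotation must contain a 'sample' column", call. = FALSE)
  if (anyDuplicated(ann$sample))
    stop("duplicate sample identifier(s) in annotation", call. = FALSE)
  ann
}

#' @rdname readSampleAnnotation
#' @export
writeSampleAnnotation <- function(ann, path) {
  data.table::fwrite(as.data.frame(ann), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' One tab-separated line per term: id, description, then one or more gene
#' ids.  Round trips preserve the sets up to member order.
#'
#' @param path File path.
#' @return `readGmt`: a [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection(structure(list(), names = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  GeneSetCollection(sets, setNames(desc, ids))
}

#' @rdname readGmt
#' @param collection A [GeneSetCollection-class] (or named list of character
#'   vectors).
#' @export
writeGmt <- function(collection, path) {
  if (!is(collection, "GeneSetCollection"))
    collection <- GeneSetCollection(collection)
  lines <- vapply(names(collection@sets), function(id)
    paste(c(id, collection@descriptions[[id]], collection@sets[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write promoter sequences in FASTA format
#'
#' Sequences are uppercased and validated to the alphabet A/C/G/T/N (N bases
#' score as background in motif scanning).
#'
#' @param path File path.
#' @return `readPromoters`: a [Biostrings::DNAStringSet] named by gene id.
#' @export
readPromoters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character in record '%s' at position %d",
                 names(seqs)[i], bad[i]), call. = FALSE)
  }
  Biostrings::DNAStringSet(seqs)
}

#' @rdname readPromoters
#' @param promoters A [Biostrings::DNAStringSet] or named character vector.
#' @export
writePromoters <- function(promoters, path) {
  if (!is(promoters, "DNAStringSet"))
    promoters <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}

#' Read / write motif matrices in a minimal MEME-like text format
#'
#' Each motif is a block starting with `MOTIF <id>` followed by one line per
#' position with four probabilities (A C G T).  Rows whose sum deviates from
#' 1 by more than 1e-6 are renormalized with a warning; rows summing to zero
#' or below are an error.
#'
#' @param path File path.
#' @param pseudocount Passed to [MotifMatrix()].
#' @return `readMotifs`: a named list of [MotifMatrix-class] objects.
#' @export
readMotifs <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path, call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- list()
  for (b in seq_along(starts)) {
    id <- sub("^MOTIF\\s+", "", lines[starts[b]])
    body <- lines[(starts[b] + 1L):ends[b]]
    body <- body[nzchar(body)]
    rows <- lapply(seq_along(body), function(i) {
      p <- suppressWarnings(as.numeric(strsplit(body[i], "\\s+")[[1]]))
      if (length(p) != 4L || anyNA(p))
        stop(sprintf("motif '%s': row %d is not 4 numbers", id, i),
             call. = FALSE)
      s <- sum(p)
      if (s <= 0)
        stop(sprintf("motif '%s': row %d sums to zero", id, i),
             call. = FALSE)
      if (abs(s - 1) > 1e-3)
        warning(sprintf("motif '%s': row %d renormalized (sum %.4g)",
                        id, i, s))
      p / s
    })
    motifs[[id]] <- MotifMatrix(id, t(do.call(rbind, rows)),
                                pseudocount = pseudocount)
  }
  motifs
}

#' @rdname readMotifs
#' @param motifs Named list of [MotifMatrix-class] objects.
#' @export
writeMotifs <- function(motifs, path) {
  if (is(motifs, "MotifMatrix")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# minimal motif matrix format: columns A C G T", con)
  for (m in motifs) {
    writeLines(paste("MOTIF", m@id), con)
    writeLines(apply(t(m@mat), 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [hierarchicalCluster()]).
#' @param path File path.
#' @export
writeNewick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
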