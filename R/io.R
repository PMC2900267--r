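# ---------------------------------------------------------------------------
# Domain containers
# ---------------------------------------------------------------------------

#' Construct an expression matrix container
#'
#' Bundles a genes x arrays matrix of log2-scale expression values with the
#' design that maps each array to its (time) group. All downstream stages
#' consume this container.
#'
#' @param values Numeric matrix, genes in rows, arrays in columns. Row and
#'   column names are taken as gene and array ids if `gene_ids` /
#'   `array_ids` are not given.
#' @param design Data frame with columns `array_id` and `group`; one row per
#'   array. Group order is the order of first appearance.
#' @param gene_ids,array_ids Optional character vectors overriding dimnames.
#' @return An object of class `ExpressionMatrix` with elements `values`
#'   (named matrix), `design` (data frame) and `groups` (ordered group
#'   labels).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
#' des <- data.frame(array_id = paste0("a", 1:4),
#'                   group = rep(c("day0", "day2"), each = 2))
#' expression_matrix(m, des)
#' @export
expression_matrix <- function(values, design, gene_ids = NULL,
                              array_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(array_ids)) colnames(values) <- array_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene and array ids", call. = FALSE)
  if (!is.numeric(values) || anyNA(values))
    stop("expression values must be numeric and complete (no NA)",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate array ids", call. = FALSE)
  design <- as.data.frame(design)
  if (!all(c("array_id", "group") %in% names(design)))
    stop("design needs columns array_id and group", call. = FALSE)
  design$array_id <- as.character(design$array_id)
  design$group <- as.character(design$group)
  if (anyDuplicated(design$array_id))
    stop("duplicate array ids in design", call. = FALSE)
  missing <- setdiff(colnames(values), design$array_id)
  if (length(missing))
    stop("arrays absent from design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  design <- design[match(colnames(values), design$array_id), , drop = FALSE]
  rownames(design) <- NULL
  groups <- unique(design$group)
  sizes <- table(factor(design$group, levels = groups))
  if (length(groups) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 arrays each", call. = FALSE)
  structure(list(values = values, design = design, groups = groups),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  sizes <- table(factor(x$design$group, levels = x$groups))
  cat(sprintf("ExpressionMatrix: %d genes x %d arrays\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s(n=%d)", x$groups, sizes),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Group factor of an expression matrix
#'
#' @param em An `ExpressionMatrix`.
#' @return Factor of length `ncol(em$values)` with levels in group order.
#' @export
group_factor <- function(em) {
  factor(em$design$group, levels = em$groups)
}

#' Construct a promoter sequence set
#'
#' @param sequences Named character vector of nucleotide sequences over
#'   A, C, G, T, N (lower case accepted, stored upper case). Names are gene
#'   ids.
#' @param upstream_bp,downstream_bp Window the sequences were extracted
#'   from, in bp relative to the coding-region start. Defaults 1000 and 200,
#'   the window used throughout the pipeline. Recorded as metadata with
#'   every set.
#' @return Object of class `PromoterSet`.
#' @export
promoter_set <- function(sequences, upstream_bp = 1000, downstream_bp = 200) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("promoter sequences need unique gene-id names", call. = FALSE)
  ids <- names(sequences)
  sequences <- toupper(as.character(sequences))
  names(sequences) <- ids
  if (any(!nzchar(sequences)))
    stop("empty promoter sequence", call. = FALSE)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("promoter sequences restricted to A,C,G,T,N; offending ids: ",
         paste(head(names(sequences)[bad], 5), collapse = ", "),
         call. = FALSE)
  structure(list(sequences = sequences,
                 upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet: %d sequences, window %d bp up / %d bp down\n",
              length(x$sequences), x$upstream_bp, x$downstream_bp))
  invisible(x)
}

#' @export
length.PromoterSet <- function(x) length(x$sequences)

#' Construct a position weight matrix
#'
#' @param motif_id Motif name.
#' @param mat 4 x L non-negative matrix of counts or weights, rows in order
#'   A, C, G, T.
#' @param dialect Source dialect, `"transfac"` or `"jaspar"`.
#' @return Object of class `PWM`.
#' @export
pwm <- function(motif_id, mat, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L)
    stop("PWM must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(mat) < 4L)
    stop("PWM length must be >= 4", call. = FALSE)
  if (any(mat < 0) || anyNA(mat))
    stop("PWM entries must be non-negative", call. = FALSE)
  if (any(colSums(mat) == 0))
    stop("PWM column with all-zero counts", call. = FALSE)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), mat = mat,
                 dialect = dialect), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s (%s dialect), length %d\n", x$motif_id, x$dialect,
              ncol(x$mat)))
  invisible(x)
}

#' Construct an annotation (gene set) collection
#'
#' @param terms Data frame with columns `term_id`, `term_class`,
#'   `description`.
#' @param members Named list (names = term ids) of character vectors of
#'   member gene ids; duplicates within a term are removed.
#' @return Object of class `AnnotationSet`.
#' @export
annotation_set <- function(terms, members) {
  terms <- as.data.frame(terms)
  if (!all(c("term_id", "term_class", "description") %in% names(terms)))
    stop("terms needs columns term_id, term_class, description",
         call. = FALSE)
  if (anyDuplicated(terms$term_id))
    stop("duplicate term ids", call. = FALSE)
  if (!setequal(names(members), terms$term_id))
    stop("members must be named by the term ids", call. = FALSE)
  members <- lapply(members[terms$term_id], function(m) unique(as.character(m)))
  if (any(lengths(members) == 0L))
    stop("term with no member genes", call. = FALSE)
  structure(list(terms = terms, members = members), class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d terms, %d distinct genes\n",
              nrow(x$terms), length(unique(unlist(x$members)))))
  invisible(x)
}

#' @export
length.AnnotationSet <- function(x) nrow(x$terms)

# ---------------------------------------------------------------------------
# Readers
# ---------------------------------------------------------------------------

#' Read an expression matrix and its design table
#'
#' The matrix file is tab-separated with a header of array ids and gene ids
#' in the first column; the design file is tab-separated with columns
#' `array_id` and `group`. Group order is the order of first appearance in
#' the design file.
#'
#' @param path Path of the expression TSV.
#' @param design_path Path of the design TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, design_path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("expression file has no array columns",
                           call. = FALSE)
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                     dimnames = list(gene_ids,
                                                     colnames(vals))))
  if (anyNA(storage))
    stop("non-numeric or missing expression values in ", path, call. = FALSE)
  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       colClasses = "character")
  expression_matrix(storage, design)
}

#' Write an expression matrix and design table
#'
#' @param em An `ExpressionMatrix`.
#' @param path,design_path Output TSV paths.
#' @export
write_expression <- function(em, path, design_path = NULL) {
  tab <- data.frame(gene_id = rownames(em$values),
                    format(em$values, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    write.table(em$design, design_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Record ids are gene ids; sequences are upper-cased and validated against
#' the A,C,G,T,N alphabet.
#'
#' @param path FASTA file path.
#' @param upstream_bp,downstream_bp Window metadata recorded with the set.
#' @return A [promoter_set()].
#' @export
read_fasta_promoters <- function(path, upstream_bp = 1000,
                                 downstream_bp = 200) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L])
    stop("not a FASTA file: ", path, call. = FALSE)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  # a header immediately followed by another header leaves a gap in rec
  if (length(seqs) != length(ids) ||
      !identical(sort(as.integer(names(seqs))), seq_along(ids)))
    stop("empty FASTA record in ", path, call. = FALSE)
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, call. = FALSE)
  promoter_set(seqs, upstream_bp, downstream_bp)
}

#' Write a promoter set as FASTA
#'
#' @param ps A `PromoterSet`.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta_promoters <- function(ps, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(ps$sequences)) {
    s <- ps$sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id), substring(s, starts,
                                            pmin(starts + width - 1L,
                                                 nchar(s)))), con)
  }
  invisible(path)
}

#' Read position weight matrices
#'
#' Supports two plain-text dialects. TRANSFAC: blocks delimited by `//`,
#' the motif name taken from the `NA` line when present, else `ID`; matrix
#' lines start with a position number followed by four counts (a trailing
#' consensus letter is ignored). JASPAR: `>` header lines followed by four
#' rows `A [ ... ]` through `T [ ... ]` (bare four-row blocks without
#' brackets are also accepted).
#'
#' @param path Matrix file path.
#' @param dialect `"transfac"` or `"jaspar"`.
#' @return List of [pwm()] objects.
#' @export
read_pwms <- function(path, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  switch(dialect,
         transfac = parse_transfac(lines),
         jaspar = parse_jaspar(lines))
}

parse_transfac <- function(lines) {
  lines <- trimws(lines)
  blocks <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (blk in blocks) {
    blk <- blk[!grepl("^//", blk) & nzchar(blk)]
    if (!length(blk)) next
    take_tag <- function(tag) {
      hit <- grep(paste0("^", tag, "\\s+"), blk, value = TRUE)
      if (length(hit)) trimws(sub(paste0("^", tag, "\\s+"), "", hit[1L]))
      else NULL
    }
    id <- take_tag("NA")
    if (is.null(id)) id <- take_tag("ID")
    mat_lines <- grep("^[0-9]+\\s", blk, value = TRUE)
    if (!length(mat_lines)) {
      if (is.null(id)) next   # header-only block (e.g. VV lines)
      stop("TRANSFAC block ", id, " has no matrix lines", call. = FALSE)
    }
    if (is.null(id))
      stop("TRANSFAC block without NA/ID line", call. = FALSE)
    rows <- lapply(strsplit(mat_lines, "\\s+"), function(f) {
      f <- f[-1L]                        # drop position index
      if (length(f) == 5L) f <- f[1:4]   # drop consensus letter
      if (length(f) != 4L)
        stop("TRANSFAC matrix line with ", length(f),
             " fields (need 4 counts)", call. = FALSE)
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v)) stop("non-numeric TRANSFAC count", call. = FALSE)
      v
    })
    m <- t(do.call(rbind, rows))  # positions were rows; PWM wants 4 x L
    out[[length(out) + 1L]] <- pwm(id, m, dialect = "transfac")
  }
  out
}

parse_jaspar <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("JASPAR file without '>' headers", call. = FALSE)
  blocks <- split(lines, cumsum(hdr))
  lapply(unname(blocks), function(blk) {
    id <- sub("^>\\s*(\\S+).*$", "\\1", blk[1L])
    body <- blk[-1L]
    if (length(body) != 4L)
      stop("JASPAR block ", id, " needs exactly 4 matrix rows",
           call. = FALSE)
    base_of <- sub("^([ACGTacgt]).*$", "\\1", body)
    rows <- lapply(body, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v)) stop("non-numeric JASPAR count", call. = FALSE)
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged JASPAR matrix in block ", id, call. = FALSE)
    m <- do.call(rbind, rows)
    ord <- match(c("A", "C", "G", "T"), toupper(base_of))
    if (anyNA(ord)) ord <- 1:4   # bare block: assume A,C,G,T order
    pwm(id, m[ord, , drop = FALSE], dialect = "jaspar")
  })
}

#' Write position weight matrices
#'
#' @param pwms List of `PWM` objects.
#' @param path Output path.
#' @param dialect Output dialect, `"jaspar"` or `"transfac"`.
#' @export
write_pwms <- function(pwms, path, dialect = c("jaspar", "transfac")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    m <- p$mat
    if (dialect == "jaspar") {
      writeLines(paste0(">", p$motif_id), con)
      for (b in c("A", "C", "G", "T"))
        writeLines(sprintf("%s [ %s ]", b,
                           paste(format(m[b, ], digits = 15, trim = TRUE,
                                        scientific = FALSE),
                                 collapse = " ")), con)
    } else {
      writeLines(c("XX", paste("NA ", p$motif_id),
                   "P0      A      C      G      T"), con)
      for (j in seq_len(ncol(m)))
        writeLines(paste(c(sprintf("%02d", j),
                           format(m[, j], digits = 15, trim = TRUE,
                                  scientific = FALSE)),
                         collapse = "  "), con)
      writeLines("//", con)
    }
  }
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' Tab-separated rows: term id, description, member genes (one per column).
#' A description of the form `CLASS|text` carries the term class (e.g.
#' `GO_BP|response to wounding`); otherwise the class is `"unclassified"`.
#'
#' @param path GMT file path.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT row with no member genes (line ", bad[1L], ")", call. = FALSE)
  term_id <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  has_class <- grepl("|", desc, fixed = TRUE)
  term_class <- ifelse(has_class, sub("\\|.*$", "", desc), "unclassified")
  description <- ifelse(has_class, sub("^[^|]*\\|", "", desc), desc)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- term_id
  annotation_set(data.frame(term_id = term_id, term_class = term_class,
                            description = description),
                 members)
}

#' Write gene-set annotations in GMT format
#'
#' @param ann An `AnnotationSet`.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  rows <- vapply(seq_len(nrow(ann$terms)), function(i) {
    t <- ann$terms[i, ]
    desc <- if (t$term_class == "unclassified") t$description else
      paste0(t$term_class, "|", t$description)
    paste(c(t$term_id, desc, ann$members[[t$term_id]]), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
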