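## Readers and writers for the package's plain-text formats.  All readers
## validate rather than coerce; all writers emit deterministically ordered
## tables so repeated runs are diffable.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    ...)
}

#' Read / write a gene-by-sample expression matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' Duplicate gene ids, missing values and non-numeric cells are rejected
#' (the scoring model assumes complete data).
#'
#' @param path file path
#' @return numeric matrix genes x samples
#' @export
read_expression <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("malformed expression file: need gene + sample columns")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene id(s): ",
                        paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in expression matrix")
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- genes
  m
}

#' @rdname read_expression
#' @param x numeric matrix genes x samples
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read / write genomic regions (genes, elements, loops)
#'
#' Coordinates are 0-based half-open (BED convention).  `genes` are BED6
#' (chrom, start, end, name, score, strand; the TSS is the start on the
#' plus strand and the end on the minus strand); `elements` add `kind`
#' (PRE/DRE) and the linked `gene` for PREs; `loops` are BEDPE with the
#' anchor element ids in the name field (`anchor1;anchor2`).
#'
#' @param path file path
#' @param kind one of `"genes"`, `"elements"`, `"loops"`
#' @return data frame in the landscape's internal layout
#' @export
read_regions <- function(path, kind = c("genes", "elements", "loops")) {
  kind <- match.arg(kind)
  df <- read_tsv(path)
  check_coords <- function(start, end, what) {
    if (any(start < 0)) stop(what, ": negative coordinates")
    if (any(start >= end)) stop(what, ": start must be < end")
  }
  if (kind == "genes") {
    need <- c("chrom", "start", "end", "name", "score", "strand")
    if (!all(need %in% names(df))) stop("genes: missing columns")
    check_coords(df$start, df$end, "genes")
    data.frame(gene = df$name, chrom = df$chrom, strand = df$strand,
               tss = ifelse(df$strand == "+", df$start, df$end),
               start = df$start, end = df$end, stringsAsFactors = FALSE)
  } else if (kind == "elements") {
    need <- c("chrom", "start", "end", "name", "kind")
    if (!all(need %in% names(df))) stop("elements: missing columns")
    check_coords(df$start, df$end, "elements")
    if (!all(df$kind %in% c("PRE", "DRE"))) stop("elements: bad kind value")
    gene <- if ("gene" %in% names(df)) as.character(df$gene) else
      NA_character_
    gene[gene %in% c("", ".")] <- NA
    if (any(df$kind == "PRE" & is.na(gene)))
      stop("elements: PRE without linked gene")
    data.frame(element = df$name, kind = df$kind, chrom = df$chrom,
               start = df$start, end = df$end, gene = gene,
               stringsAsFactors = FALSE)
  } else {
    need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name")
    if (!all(need %in% names(df))) stop("loops: missing columns")
    check_coords(df$start1, df$end1, "loops")
    check_coords(df$start2, df$end2, "loops")
    anchors <- strsplit(df$name, ";", fixed = TRUE)
    if (any(lengths(anchors) != 2)) stop("loops: malformed anchor names")
    data.frame(anchor1 = vapply(anchors, `[`, "", 1),
               anchor2 = vapply(anchors, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
}

#' Write a regulatory landscape to a directory
#'
#' Emits `genes.bed`, `elements.bed`, `loops.bedpe` and `binding.tsv`
#' (all TSV with headers).
#'
#' @param landscape a `regulatory_landscape`
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- landscape$genes[order(landscape$genes$gene), ]
  write_tsv(data.frame(chrom = g$chrom, start = g$start, end = g$end,
                       name = g$gene, score = 0, strand = g$strand),
            file.path(dir, "genes.bed"))
  el <- landscape$elements[order(landscape$elements$element), ]
  write_tsv(data.frame(chrom = el$chrom, start = el$start, end = el$end,
                       name = el$element, kind = el$kind,
                       gene = ifelse(is.na(el$gene), ".", el$gene)),
            file.path(dir, "elements.bed"))
  el_at <- function(id, col) el[[col]][match(id, el$element)]
  lp <- landscape$loops
  lp <- lp[order(lp$anchor1, lp$anchor2), , drop = FALSE]
  write_tsv(data.frame(chrom1 = el_at(lp$anchor1, "chrom"),
                       start1 = el_at(lp$anchor1, "start"),
                       end1 = el_at(lp$anchor1, "end"),
                       chrom2 = el_at(lp$anchor2, "chrom"),
                       start2 = el_at(lp$anchor2, "start"),
                       end2 = el_at(lp$anchor2, "end"),
                       name = paste(lp$anchor1, lp$anchor2, sep = ";")),
            file.path(dir, "loops.bedpe"))
  b <- landscape$binding
  b <- b[order(b$tf, b$element, b$evidence, b$cell_context), , drop = FALSE]
  write_tsv(b, file.path(dir, "binding.tsv"))
  invisible(dir)
}

#' Read a regulatory landscape from a directory
#' @param dir directory written by [write_landscape()]
#' @return a `regulatory_landscape`
#' @export
read_landscape <- function(dir) {
  genes <- read_regions(file.path(dir, "genes.bed"), "genes")
  elements <- read_regions(file.path(dir, "elements.bed"), "elements")
  loops <- read_regions(file.path(dir, "loops.bedpe"), "loops")
  binding <- read_tsv(file.path(dir, "binding.tsv"))
  bad <- setdiff(c(loops$anchor1, loops$anchor2, binding$element),
                 elements$element)
  if (length(bad)) stop("unknown element id(s): ",
                        paste(unique(bad), collapse = ", "))
  structure(list(genes = genes, elements = elements, loops = loops,
                 binding = binding),
            class = "regulatory_landscape")
}

#' Read / write a network edge list
#'
#' TSV edge list with `regulator` and `target` columns plus optional
#' metadata (probability, support, sign, ...).  Self-loop rows are
#' rejected for learning and prior inputs.
#'
#' @param path file path
#' @param nodes optional node universe (defaults to the edge endpoints)
#' @return a `gene_network`
#' @export
read_network <- function(path, nodes = NULL) {
  df <- read_tsv(path)
  if (!all(c("regulator", "target") %in% names(df)))
    stop("network file needs regulator and target columns")
  gene_network(df, nodes = nodes)
}

#' @rdname read_network
#' @param net a `gene_network`
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  write_tsv(net$edges, path)
  invisible(path)
}

#' Read / write a prior table
#' @param path TSV with columns regulator, target, probability, evidence,
#'   cell_context, topology
#' @return a `prior_table`
#' @export
read_prior_table <- function(path) {
  df <- read_tsv(path)
  for (col in c("evidence", "cell_context", "topology"))
    if (!is.null(df[[col]])) df[[col]][df[[col]] == "."] <- NA
  prior_table(df)
}

#' @rdname read_prior_table
#' @param prior a `prior_table`
#' @export
write_prior_table <- function(prior, path) {
  df <- as.data.frame(prior)
  df$cell_context[is.na(df$cell_context)] <- "."
  df$topology[is.na(df$topology)] <- "."
  write_tsv(df, path)
  invisible(path)
}
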