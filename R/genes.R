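#' Construct a gene model table
#'
#' Gene models carry the locus span, strand, TSS and exon structure needed
#' for promoter/exonic/intronic/intergenic annotation and nearest-gene
#' linking. Coordinates are 0-based half-open; the TSS is `start` for
#' plus-strand genes and `end - 1` for minus-strand genes.
#'
#' @param df data frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end`, `biotype`, and a list column
#'   `exons` of data frames with `start`/`end` per gene.
#' @return a `GeneTable` (data.frame subclass) sorted by `(chrom, start)`,
#'   with a derived `tss` column.
#' @export
gene_table <- function(df) {
  req <- c("gene_id", "chrom", "strand", "start", "end", "exons")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_input("gene table missing columns: %s",
                               paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (is.null(df$gene_name)) df$gene_name <- df$gene_id
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  df$chrom <- as.character(df$chrom)
  df$gene_id <- as.character(df$gene_id)
  validate_intervals(df, "gene")
  if (anyDuplicated(df$gene_id))
    stop_input("duplicate gene_id '%s'", df$gene_id[duplicated(df$gene_id)][1])
  if (!all(df$strand %in% c("+", "-")))
    stop_input("gene strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0)
      stop_input("gene '%s' has zero exons", df$gene_id[i])
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < df$start[i]) || any(ex$end > df$end[i]))
      stop_input("gene '%s': exon outside locus", df$gene_id[i])
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop_input("gene '%s': overlapping exons", df$gene_id[i])
    df$exons[[i]] <- ex[, c("start", "end"), drop = FALSE]
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df <- df[genomic_order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  keep <- c("gene_id", "gene_name", "chrom", "strand", "start", "end",
            "tss", "biotype", "exons")
  structure(df[keep], class = c("GeneTable", "data.frame"))
}

#' @export
print.GeneTable <- function(x, ...) {
  cat(sprintf("GeneTable: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x)[
    c("gene_id", "chrom", "strand", "start", "end", "tss", "biotype")], 6))
  invisible(x)
}

#' Read gene models from GTF or BED12
#'
#' GTF coordinates (1-based inclusive) are converted to 0-based half-open.
#' Gene loci come from `gene` features when present, otherwise from the
#' span of each gene's exons; a `gene` feature without any exon is an
#' error, as is a duplicated gene id.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed12"`.
#' @return a [gene_table()].
#' @export
read_genes <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("gene file not found: %s", path)
  if (format == "gtf") read_genes_gtf(path) else read_genes_bed12(path)
}

read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop_input("%s: GTF records lack gene_id", path)
  type <- as.character(md$type)
  exons <- gr[type == "exon"]
  genes <- gr[type == "gene"]
  exon_ids <- unique(S4Vectors::mcols(exons)$gene_id)
  if (length(genes)) {
    gid <- S4Vectors::mcols(genes)$gene_id
    if (anyDuplicated(gid))
      stop_input("%s: duplicate gene_id '%s'", path, gid[duplicated(gid)][1])
    no_exon <- setdiff(gid, exon_ids)
    if (length(no_exon))
      stop_input("%s: gene '%s' has zero exons", path, no_exon[1])
  }
  if (!length(exons)) stop_input("%s: no exon features", path)
  ex_gid <- as.character(S4Vectors::mcols(exons)$gene_id)
  sp <- split(seq_along(exons), ex_gid)
  build_row <- function(idx) {
    sub <- exons[idx]
    ch <- unique(as.character(GenomicRanges::seqnames(sub)))
    st <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(ch) != 1 || length(st) != 1)
      stop_input("%s: gene '%s' spans multiple chromosomes/strands",
                 path, ex_gid[idx[1]])
    list(chrom = ch, strand = st,
         exons = data.frame(start = GenomicRanges::start(sub) - 1,
                            end = as.numeric(GenomicRanges::end(sub))))
  }
  rows <- lapply(sp, build_row)
  gid <- names(sp)
  # per-gene attributes: prefer the gene feature's record, fall back to exons
  all_gid <- as.character(md$gene_id)
  pick <- ifelse(is.na(match(gid, all_gid[type == "gene"])),
                 match(gid, all_gid),
                 which(type == "gene")[match(gid, all_gid[type == "gene"])])
  md_first <- md[pick, , drop = FALSE]
  gname <- if (!is.null(md_first$gene_name)) as.character(md_first$gene_name) else gid
  biot <- md_first$gene_biotype %||% md_first$gene_type
  biot <- if (is.null(biot)) rep("protein_coding", length(gid)) else as.character(biot)
  locus <- lapply(gid, function(g) {
    if (length(genes)) {
      hit <- which(S4Vectors::mcols(genes)$gene_id == g)
      if (length(hit))
        return(c(GenomicRanges::start(genes)[hit[1]] - 1,
                 GenomicRanges::end(genes)[hit[1]]))
    }
    ex <- rows[[g]]$exons
    c(min(ex$start), max(ex$end))
  })
  gene_table(data.frame(
    gene_id = gid,
    gene_name = ifelse(is.na(gname), gid, gname),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(locus, `[`, 0, 1),
    end = vapply(locus, `[`, 0, 2),
    biotype = ifelse(is.na(biot), "protein_coding", biot),
    exons = I(lapply(rows, `[[`, "exons")),
    stringsAsFactors = FALSE))
}

read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr))
    stop_input("%s: empty BED12 file", path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$blocks)) stop_input("%s: not BED12 (no block structure)", path)
  gid <- as.character(md$name)
  if (anyDuplicated(gid))
    stop_input("%s: duplicate gene_id '%s'", path, gid[duplicated(gid)][1])
  exons <- lapply(seq_along(gr), function(i) {
    bl <- md$blocks[[i]]  # block ranges relative to the locus, 1-based
    data.frame(start = GenomicRanges::start(gr)[i] - 1 + GenomicRanges::start(bl) - 1,
               end = GenomicRanges::start(gr)[i] - 1 + GenomicRanges::end(bl))
  })
  gene_table(data.frame(
    gene_id = gid, gene_name = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    biotype = "protein_coding",
    exons = I(exons), stringsAsFactors = FALSE))
}

#' Write gene models as GTF
#'
#' One `gene` line plus one `exon` line per exon, 1-based inclusive,
#' round-trippable through [read_genes()].
#'
#' @param genes a [gene_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  stopifnot(inherits(genes, "GeneTable"))
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     genes$gene_id[i], genes$gene_name[i], genes$biotype[i])
    lines <- c(lines,
               sprintf("%s\tglrscope\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       genes$chrom[i], as.integer(genes$start[i] + 1),
                       as.integer(genes$end[i]), genes$strand[i], attrs))
    ex <- genes$exons[[i]]
    lines <- c(lines,
               sprintf("%s\tglrscope\texon\t%d\t%d\t.\t%s\t.\t%s",
                       genes$chrom[i], as.integer(ex$start + 1),
                       as.integer(ex$end), genes$strand[i], attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Nearest TSS to genomic positions
#'
#' For each query position, the gene whose TSS minimises `|tss - pos|`;
#' ties are broken toward the lexicographically smaller `gene_id`.
#' The signed distance is `pos - tss` (positive when the position lies at
#' a higher coordinate than the TSS).
#'
#' @param chrom,pos parallel vectors of query chromosome and 0-based bp.
#' @param genes a [gene_table()].
#' @param error_on_missing if `TRUE` (default) a query chromosome with no
#'   gene is an error; otherwise it yields `NA` with a warning.
#' @param warn emit the warning for gene-free chromosomes when
#'   `error_on_missing = FALSE` (callers where that case is expected,
#'   such as location annotation, silence it).
#' @return data.frame with `gene_id`, `tss`, `distance` (signed),
#'   `abs_distance` per query.
#' @export
nearest_tss <- function(chrom, pos, genes, error_on_missing = TRUE,
                        warn = TRUE) {
  stopifnot(inherits(genes, "GeneTable"), length(chrom) == length(pos))
  out <- data.frame(gene_id = rep(NA_character_, length(pos)),
                    tss = NA_real_, distance = NA_real_, abs_distance = NA_real_)
  for (ch in unique(chrom)) {
    qsel <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) {
      if (error_on_missing)
        stop_input("nearest_tss: no gene on chromosome '%s'", ch)
      if (warn)
        warning(sprintf("no gene on chromosome '%s'; %d site(s) unassigned",
                        ch, length(qsel)), call. = FALSE)
      next
    }
    # collapse genes sharing a TSS to the lexicographically smallest gene_id,
    # so every tie (equal |tss - pos|) resolves to the smaller id
    ord <- order(g$tss, g$gene_id, method = "radix")
    tss <- g$tss[ord]; gid <- g$gene_id[ord]
    first <- !duplicated(tss)
    utss <- tss[first]; ugid <- gid[first]
    idx <- findInterval(pos[qsel], utss)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(utss))
    dlo <- abs(pos[qsel] - utss[lo]); dhi <- abs(pos[qsel] - utss[hi])
    use_hi <- dhi < dlo | (dhi == dlo & ugid[hi] < ugid[lo])
    pick <- ifelse(use_hi, hi, lo)
    out$gene_id[qsel] <- ugid[pick]
    out$tss[qsel] <- utss[pick]
    out$distance[qsel] <- pos[qsel] - utss[pick]
    out$abs_distance[qsel] <- abs(pos[qsel] - utss[pick])
  }
  out
}
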