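# ---- variant and table I/O -------------------------------------------------

variant_key <- function(chrom, pos, ref, alt)
  paste(chrom, pos, ref, alt, sep = ":")

#' Read a gene alias table
#'
#' Two-column TSV, alias then canonical symbol.
#'
#' @param path file path.
#' @return named character vector (alias -> canonical).
#' @export
read_alias_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("alias table needs two columns: ", path)
  stats::setNames(df[[2]], df[[1]])
}

#' Read a per-variant numeric sidecar table
#'
#' Two-column TSV: variant key `"chrom:pos:ref:alt"`, then a numeric value
#' (MAF or pathogenicity).
#'
#' @param path file path.
#' @return named numeric vector keyed by variant.
#' @export
read_variant_sidecar <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("sidecar table needs two columns: ", path)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

# extract one key from a semicolon-joined INFO string ("" if absent)
.info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else "", "")
}

# gene and consequence from an ANN/CSQ annotation (first entry):
# pipe-separated, field 2 = consequence class, field 4 = gene symbol
.ann_gene_csq <- function(info) {
  ann <- .info_field(info, "ANN")
  csq <- .info_field(info, "CSQ")
  ann[!nzchar(ann)] <- csq[!nzchar(ann)]
  first <- vapply(strsplit(ann, ","), function(x)
    if (length(x) > 0L) x[1] else "", "")
  fields <- strsplit(first, "|", fixed = TRUE)
  list(gene = vapply(fields, function(f)
         if (length(f) >= 4L) f[4] else "", ""),
       consequence = vapply(fields, function(f)
         if (length(f) >= 2L) f[2] else "", ""))
}

#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file (via the vcfR package) into one record per ALT
#' allele carried by the first sample's genotype.  Zygosity is `hom` when
#' both genotype alleles equal the ALT index, `het` otherwise; `0/0` and
#' missing genotypes are skipped, and a multi-allelic `1/2` genotype yields
#' two het records.  Gene symbols come from an `ANN`/`CSQ` annotation
#' (first entry, gene in pipe-field 4), a `GENE=` INFO key, or a per-variant
#' sidecar map; when both are present the sidecar wins.  MAF is taken from
#' an `AF`-like INFO key or the MAF sidecar; pathogenicity from its
#' sidecar.  Missing pathogenicity on an exonic frameshift consequence is
#' set to 1.
#'
#' @param path VCF path (plain or bgzipped).
#' @param gene_map optional named character vector: variant key
#'   `"chrom:pos:ref:alt"` -> gene symbol.
#' @param alias optional gene alias table (named character vector).
#' @param maf_table,patho_table optional named numeric sidecars keyed by
#'   variant key.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `gene`, `maf`, `pathogenicity`, `consequence`, `source`.
#' @export
read_vcf <- function(path, gene_map = NULL, alias = NULL,
                     maf_table = NULL, patho_table = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  info[is.na(info)] <- ""
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample genotype column: ", path)
  fmt <- vcf@gt[, 1]
  smp <- vcf@gt[, 2]
  gt <- mapply(function(f, s) {
    flds <- strsplit(f, ":", fixed = TRUE)[[1]]
    vals <- strsplit(s, ":", fixed = TRUE)[[1]]
    i <- match("GT", flds)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }, fmt, smp, USE.NAMES = FALSE)

  annot <- .ann_gene_csq(info)
  gene_info <- .info_field(info, "GENE")
  af_info <- .info_field(info, "AF")

  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(vcf@fix))) {
    g <- gt[i]
    if (is.na(g) || !grepl("^[0-9.]+[/|][0-9.]+$", g)) { skipped <- skipped + 1L; next }
    alleles <- strsplit(g, "[/|]")[[1]]
    if (all(alleles %in% c("0", "."))) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (ai in unique(alleles[alleles != "0" & alleles != "."])) {
      idx <- as.integer(ai)
      if (is.na(idx) || idx > length(alts)) { skipped <- skipped + 1L; next }
      zyg <- if (all(alleles == ai)) "hom" else "het"
      key <- variant_key(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[idx])
      gene <- if (!is.null(gene_map) && key %in% names(gene_map))
        unname(gene_map[key])
      else if (nzchar(annot$gene[i])) annot$gene[i]
      else if (nzchar(gene_info[i])) gene_info[i]
      else ""
      if (!nzchar(gene)) {
        stop("no gene symbol for variant ", key,
             ": supply an ANN/CSQ or GENE INFO annotation, ",
             "or a per-variant gene sidecar map")
      }
      if (!is.null(alias) && gene %in% names(alias)) gene <- unname(alias[gene])
      maf <- if (!is.null(maf_table) && key %in% names(maf_table))
        unname(maf_table[key])
      else if (nzchar(af_info[i]))
        as.numeric(strsplit(af_info[i], ",")[[1]][idx]) else NA_real_
      patho <- if (!is.null(patho_table) && key %in% names(patho_table))
        unname(patho_table[key]) else NA_real_
      csq <- annot$consequence[i]
      if (is.na(patho) && grepl("frameshift", csq, ignore.case = TRUE))
        patho <- 1
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[idx], zygosity = zyg, gene = gene,
        maf = maf, pathogenicity = patho, consequence = csq,
        source = "vcf", stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) warning(skipped, " malformed VCF record(s) skipped")
  if (length(rows) == 0L) stop("no usable variant records in ", path)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a plain gene list as placeholder variant records
#'
#' One gene symbol per line.  Each line becomes a placeholder heterozygous
#' record (no position or allele information), so the transitive pipeline
#' can run; inheritance constraints other than `"none"` are refused
#' downstream because zygosity is unknown.
#'
#' @param path file path.
#' @param alias optional alias table.
#' @return variant data frame (same columns as [read_vcf()], `source =
#'   "gene_list"`).
#' @export
read_gene_list <- function(path, alias = NULL) {
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  if (length(genes) == 0L) stop("gene list is empty: ", path)
  if (!is.null(alias)) {
    hit <- genes %in% names(alias)
    genes[hit] <- unname(alias[genes[hit]])
  }
  data.frame(chrom = ".", pos = 1L, ref = ".", alt = ".",
             zygosity = "het", gene = genes, maf = NA_real_,
             pathogenicity = NA_real_, consequence = "",
             source = "gene_list", stringsAsFactors = FALSE)
}

# ---- matrix and tabular output ---------------------------------------------

#' Write / read a similarity matrix as square TSV
#'
#' Header row and first column carry the disease ids.
#'
#' @param m symmetric numeric matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a ranked-variant (or any) table as TSV
#'
#' Deterministic, unquoted tab-separated output.
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
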