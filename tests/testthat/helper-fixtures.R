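# Shared fixtures built in code at test time.

t6 <- make_fixture_t6()
t6_ic <- catalog_information_content(t6$catalog, t6$dag)

# toy OBO text mirroring the 6-term fixture
t6_obo_lines <- function(extra = character()) {
  c("format-version: 1.2", "",
    "[Term]", "id: T0", "name: root", "",
    "[Term]", "id: T1", "name: branch one", "is_a: T0 ! root", "",
    "[Term]", "id: T2", "name: branch two", "is_a: T0", "",
    "[Term]", "id: T3", "name: leaf three", "is_a: T1", "",
    "[Term]", "id: T4", "name: leaf four", "is_a: T1", "",
    "[Term]", "id: T5", "name: leaf five", "is_a: T2", "",
    extra)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy annotation + morbidmap files for the catalog readers
t6_annotation_lines <- c(
  "# synthetic toy annotations",
  "D1\ttoy disease 1\tT3",
  "D2\ttoy disease 2\tT4",
  "D3\ttoy disease 3\tT5",
  "D4\ttoy disease 4\tT3",
  "D4\ttoy disease 4\tT5")

t6_morbidmap_lines <- c(
  "D1\tGZ\t",
  "D2\tGZ\t",
  "D4\tGX\t")

# a session over the toy fixture with variants in GZ and GX
t6_session <- function(...) {
  v <- data.frame(
    chrom = c("chr1", "chr2"), pos = c(100L, 200L),
    ref = c("A", "C"), alt = c("G", "T"),
    zygosity = c("het", "hom"), gene = c("GZ", "GX"),
    maf = c(0.001, 0.0001), pathogenicity = c(0.9, 0.5),
    consequence = "missense_variant", source = "vcf",
    stringsAsFactors = FALSE)
  new_session(query_terms = "T3", variants = v, ...)
}
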