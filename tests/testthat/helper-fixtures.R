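# Small fixtures built in code at test time.

make_matrix <- function(genes = c("TP53", "CDKN1A", "ZNF224"),
                        samples = paste0("s", 1:4),
                        group = c("nontumor", "nontumor", "tumor", "tumor"),
                        seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(length(genes) * length(samples), 8, 1), 4),
              length(genes), length(samples),
              dimnames = list(genes, samples))
  expression_matrix(m, group)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Minimal GEO-style series-matrix fixture: 5 probes, 6 samples, sample titles
# carrying "normal"/"melanoma", two probes mapping to the same symbol.
write_series_matrix_fixture <- function(path = tempfile(fileext = ".txt")) {
  gsm <- sprintf("GSM%d", 1:6)
  titles <- c("normal skin 1", "normal skin 2", "normal skin 3",
              "melanoma 1", "melanoma 2", "melanoma 3")
  set.seed(99)
  vals <- matrix(round(rnorm(30, 8, 1), 3), 5, 6,
                 dimnames = list(sprintf("p%d", 1:5), gsm))
  vals["p2", ] <- vals["p1", ] + 2  # p1/p2 both map to TP53; p2 higher mean
  q <- function(v) paste0('"', v, '"')
  lines <- c(
    '!Series_title\t"fixture series"',
    paste(c("!Sample_title", q(titles)), collapse = "\t"),
    paste(c("!Sample_geo_accession", q(gsm)), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c('"ID_REF"', q(gsm)), collapse = "\t"),
    vapply(rownames(vals), function(p) {
      paste(c(q(p), format(vals[p, ], trim = TRUE)), collapse = "\t")
    }, character(1)),
    "!series_matrix_table_end")
  writeLines(lines, path)
  list(path = path, values = vals, titles = titles)
}

series_matrix_annotation <- function() {
  data.frame(probe_id = sprintf("p%d", 1:5),
             gene_symbol = c("TP53", "TP53", "CDKN1A", "ZNF224", "XIAP"))
}
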