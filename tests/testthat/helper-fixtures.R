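# Shared fixtures and independent oracles.

# The published counts the bundled matrix is built from, re-entered here so
# tests do not trust the shipped extdata file.
REF_COUNTS <- matrix(c(634, 6, 135, 57,
                       156, 25, 560, 91,
                       721, 84, 27, 0,
                       37, 573, 4, 218),
                     nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))

# The printed weight matrix (two decimals) the counts must regenerate.
REF_BITS <- matrix(c(1.61, -5.12, -0.62, -1.87,
                     -0.42, -3.06, 1.43, -1.19,
                     1.79, -1.31, -2.95, -7.70,
                     -2.49, 1.46, -5.70, 0.07),
                   nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))

uniform_iwm <- function(k = 25L) {
  build_iwm(counts = matrix(k, 4, 4))
}

# Independent window-score oracle: per-character table lookup written as a
# plain loop, complementing positions 5-8 by hand; no shared code with
# score_window()'s expanded-matrix path.
oracle_score <- function(word, iwm) {
  bases <- strsplit(word, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  total <- 0
  for (p in 1:8) {
    b <- bases[p]
    if (p <= 4) {
      w <- if (b == "N") min(iwm$bits[, p]) else iwm$bits[b, p]
    } else {
      q <- 9 - p
      w <- if (b == "N") min(iwm$bits[, q]) else iwm$bits[comp[[b]], q]
    }
    total <- total + w
  }
  total
}

random_region <- function(n = 400L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(records) {
  f <- withr::local_tempfile(fileext = ".fa",
                             .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), f)
  f
}

write_temp_gene_table <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

all_8mers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, b, b, stringsAsFactors = FALSE)
  do.call(paste0, g)
}
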