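## Independent oracles and small fixture builders shared across tests.

CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

## Brute-force motif checker, written as literal per-position set
## membership over a character vector -- independent of match_motif()'s
## vectorised substring implementation.
brute_match <- function(seq, variant) {
  ch <- strsplit(seq, "")[[1L]]
  excl2 <- if (variant == "legend") "D" else c("D", "E")
  is_p4 <- length(ch) >= 4L &&
    ch[1L] == "M" &&
    (ch[2L] %in% CANONICAL) && !(ch[2L] %in% excl2) &&
    ch[3L] == "P" &&
    (ch[4L] %in% CANONICAL) && ch[4L] != "P"
  if (is_p4) return("P4")
  is_p3 <- length(ch) >= 3L &&
    ch[1L] == "M" && ch[2L] == "P" &&
    (ch[3L] %in% CANONICAL) && ch[3L] != "P"
  if (is_p3) return("P3")
  "none"
}

all_4mers <- function() {
  g <- expand.grid(d = CANONICAL, c = CANONICAL, b = CANONICAL,
                   a = CANONICAL, stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c, g$d)
}

## Exhaustive upper-tail hypergeometric probability by enumerating every
## equally likely draw of n_draw items from a population of N whose first K
## items form the category.
enum_upper_tail <- function(k, K, n_draw, N) {
  if (n_draw == 0L) return(as.numeric(0L >= k))
  sets <- utils::combn(N, n_draw)
  hits <- colSums(sets <= K)
  mean(hits >= k)
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_temp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_sequences <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(CANONICAL, len, replace = TRUE), collapse = ""),
    character(1L))
}
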