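#' @importFrom stats median optimize rnbinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table combn head
NULL

# Internal sequence helpers. All sequences are held as uppercase DNA strings
# (U -> T on input); miRBase-style RNA input is accepted everywhere.

norm_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

as_rna <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(norm_seq(x))))
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Deterministic per-purpose sub-seed so adding one generator does not perturb
# the random stream of another.
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% 1000003
  as.integer((abs(seed) %% 2147483647 + h * 2017 + 1) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  withr::with_seed(stream_seed(seed, name), code)
}
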