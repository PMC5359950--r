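# Shared internals: base coding, seed derivation, raw-vector helpers.

BASES <- c("A", "C", "G", "T")
BASE_RAW <- charToRaw("ACGT")

# integer codes 1..4 for a contig, 0 for anything else
contigCodes <- function(dna) {
  r <- charToRaw(as.character(dna))
  code <- integer(length(r))
  for (i in 1:4) code[r == BASE_RAW[i]] <- i
  code
}

# Derive an independent child seed for a named stage from the root seed, so
# adding or removing a stage never perturbs the draws of another stage.
# Products stay below 2^53, result below 2^31.
stageSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 100003
  as.integer(((seed %% 2147483647) * 1103 + h * 26544 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fatal <- function(...) stop(..., call. = FALSE)
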