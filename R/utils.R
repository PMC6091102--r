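# Internal sequence encoding shared by the site counters and K2P.
# Codes: A=1, C=2, G=3, T=4, gap "-"=5, anything else (IUPAC ambiguity,
# N, ?) = 0. Codes 1:4 are the only states that enter distance or site
# calculations; 5 is kept distinct so "gap as 5th state" counting stays
# possible.
.NT_LEVELS <- c("A", "C", "G", "T", "-")

.encodeChars <- function(chars) {
  code <- match(chars, .NT_LEVELS)
  code[is.na(code)] <- 0L
  code
}

# BarcodeAlignment / DNAStringSet -> integer matrix (rows = records)
.encodeAlignment <- function(x) {
  seqs <- if (is(x, "BarcodeDataset")) x@seqs else x
  m <- as.matrix(seqs)
  enc <- .encodeChars(toupper(m))
  dim(enc) <- dim(m)
  rownames(enc) <- rownames(m)
  enc
}

# "Nepenthes_khasiana " -> "Nepenthes khasiana"
.normalizeSpecies <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

.newBarcodeDataset <- function(seqs, meta, aligned = FALSE) {
  meta <- S4Vectors::DataFrame(meta)
  names(seqs) <- as.character(meta$id)
  cls <- if (aligned) "BarcodeAlignment" else "BarcodeDataset"
  new(cls, seqs = seqs, meta = meta)
}

# percent helpers: distances are substitutions/site internally and
# percent (x100) at every reporting surface.
.toPercent <- function(x) 100 * x
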