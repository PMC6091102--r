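#' Read species-labelled barcode sequences from FASTA
#'
#' Reads a (plain or aligned) FASTA file and parses each record header
#' into species / individual / locus / accession fields under a
#' configurable schema. The full header line is kept as the record id.
#' Species names are normalised (underscores to spaces, repeated
#' whitespace collapsed); sequences are uppercased.
#'
#' The schema is an ordered list of field names joined by the delimiter
#' that separates them in the headers, e.g. the default
#' `"species|individual|locus|accession"` parses
#' `>Nepenthes_khasiana|V001|ITS|AB123456`. Recognised field names are
#' `species`, `individual`, `locus`, `accession` and `skip` (ignore a
#' column); a trailing field may be empty. Alternatively a TSV sidecar
#' with columns `id, species, individual, locus, accession` (where `id`
#' is the full FASTA header) overrides header parsing entirely.
#'
#' @param path FASTA file path.
#' @param schema Header schema string (field names + delimiter).
#' @param metadata Optional path to a TSV metadata sidecar.
#' @param aligned If `TRUE`, require equal gapped lengths and return a
#'   [BarcodeAlignment()]; otherwise a [BarcodeDataset()].
#' @return A `BarcodeDataset` (or `BarcodeAlignment`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">Nepenthes_khasiana|V001|ITS|AB123456", "ACGTACGT"), fa)
#' ds <- readBarcodeFasta(fa)
#' speciesLabels(ds)
#' @export
readBarcodeFasta <- function(path,
                             schema = "species|individual|locus|accession",
                             metadata = NULL, aligned = FALSE) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    return(.newBarcodeDataset(Biostrings::DNAStringSet(),
                              .emptyMeta(), aligned = FALSE))
  }
  chars <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTRYSWKMBDHVN-]", chars)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(chars[i], bad[i], bad[i]),
         "' in record '", names(raw)[i], "' at position ", bad[i])
  }
  headers <- names(raw)
  if (anyDuplicated(headers))
    stop("duplicate FASTA headers: ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  meta <- if (is.null(metadata)) {
    .parseHeaders(headers, schema)
  } else {
    .sidecarMeta(headers, metadata)
  }
  seqs <- Biostrings::DNAStringSet(chars)
  ds <- .newBarcodeDataset(seqs, meta)
  if (aligned) validateAlignment(ds) else ds
}

.emptyMeta <- function() {
  S4Vectors::DataFrame(id = character(), species = character(),
                       individual = character(), locus = character(),
                       accession = character())
}

.parseHeaders <- function(headers, schema) {
  fields <- strsplit(schema, "[^A-Za-z_]+")[[1L]]
  fields <- fields[nzchar(fields)]
  delim <- gsub("[A-Za-z_]+", "", schema)
  delim <- substr(delim, 1L, 1L)
  if (!nzchar(delim) || !length(fields))
    stop("unusable header schema: '", schema, "'")
  known <- c("species", "individual", "locus", "accession", "skip")
  if (!all(fields %in% known))
    stop("unknown schema field(s): ",
         paste(setdiff(fields, known), collapse = ", "))
  if (!"species" %in% fields) stop("schema must include a species field")
  parts <- strsplit(headers, delim, fixed = TRUE)
  n <- length(fields)
  get <- function(p, k) {
    if (length(p) < n - 1L || length(p) > n)
      return(NA_character_)
    if (length(p) < k) "" else trimws(p[[k]])
  }
  pick <- function(name) {
    k <- match(name, fields)
    if (is.na(k)) return(rep("", length(headers)))
    vapply(parts, get, character(1L), k = k)
  }
  species <- pick("species")
  badLen <- vapply(parts, function(p)
    length(p) < n - 1L || length(p) > n, logical(1L))
  if (any(badLen) || anyNA(species) || any(!nzchar(species))) {
    i <- which(badLen | is.na(species) | !nzchar(species))[1L]
    stop("header does not parse under schema '", schema, "': >", headers[i])
  }
  S4Vectors::DataFrame(
    id = headers,
    species = .normalizeSpecies(species),
    individual = pick("individual"),
    locus = pick("locus"),
    accession = pick("accession"))
}

.sidecarMeta <- function(headers, metadata) {
  tab <- utils::read.delim(metadata, colClasses = "character")
  need <- c("id", "species", "individual", "locus", "accession")
  if (!all(need %in% colnames(tab)))
    stop("metadata sidecar must have columns: ", paste(need, collapse = ", "))
  idx <- match(headers, tab$id)
  if (anyNA(idx))
    stop("metadata sidecar missing id(s): ",
         paste(headers[is.na(idx)], collapse = ", "))
  tab <- tab[idx, need]
  tab$species <- .normalizeSpecies(tab$species)
  if (any(!nzchar(tab$species))) stop("sidecar species must be non-empty")
  S4Vectors::DataFrame(tab, row.names = NULL)
}

#' Write a barcode dataset to FASTA
#'
#' Record ids become the FASTA headers, so a dataset read with
#' [readBarcodeFasta()] round-trips exactly.
#'
#' @param x A [BarcodeDataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBarcodeFasta <- function(x, path) {
  stopifnot(is(x, "BarcodeDataset"))
  Biostrings::writeXStringSet(x@seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Construct a barcode dataset from parts
#'
#' @param seqs Character vector or `DNAStringSet` of sequences.
#' @param species,individual,locus,accession Per-record metadata
#'   (recycled where length 1).
#' @param id Record ids; defaults to `species|individual|locus|accession`.
#' @return A `BarcodeDataset`.
#' @export
BarcodeDataset <- function(seqs, species, individual = "", locus = "",
                           accession = "", id = NULL) {
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  n <- length(seqs)
  species <- .normalizeSpecies(rep_len(as.character(species), n))
  individual <- rep_len(as.character(individual), n)
  locus <- rep_len(as.character(locus), n)
  accession <- rep_len(as.character(accession), n)
  if (is.null(id))
    id <- paste(gsub(" ", "_", species), individual, locus, accession,
                sep = "|")
  meta <- S4Vectors::DataFrame(id = as.character(id), species = species,
                               individual = individual, locus = locus,
                               accession = accession)
  .newBarcodeDataset(seqs, meta)
}

#' Validate an alignment
#'
#' Checks that every row shares one gapped length and promotes the
#' dataset to a [BarcodeAlignment()].
#'
#' @param x A `BarcodeDataset` (or anything [BarcodeDataset()] accepts).
#' @return A `BarcodeAlignment`.
#' @export
validateAlignment <- function(x) {
  stopifnot(is(x, "BarcodeDataset"))
  if (length(x@seqs) == 0L) stop("alignment must have at least one row")
  w <- Biostrings::width(x@seqs)
  if (length(unique(w)) > 1L) {
    ref <- w[1L]
    i <- which(w != ref)[1L]
    stop("ragged alignment: row '", x@meta$id[i], "' has gapped length ",
         w[i], ", expected ", ref)
  }
  new("BarcodeAlignment", seqs = x@seqs, meta = x@meta)
}

#' @rdname validateAlignment
#' @param ... Passed to [BarcodeDataset()].
#' @export
BarcodeAlignment <- function(...) validateAlignment(BarcodeDataset(...))

#' Accessors for barcode datasets
#'
#' `barcodeSeqs()` returns the `DNAStringSet`, `recordMeta()` the
#' metadata `DataFrame`, `speciesLabels()` the species of each record as
#' a character vector named by record id.
#'
#' @param x A `BarcodeDataset` or `K2PDistanceMatrix`.
#' @return See each description.
#' @name barcodeSeqs
#' @aliases recordMeta speciesLabels
NULL

#' @rdname barcodeSeqs
#' @export
setMethod("barcodeSeqs", "BarcodeDataset", function(x) x@seqs)

#' @rdname barcodeSeqs
#' @export
setMethod("recordMeta", "BarcodeDataset", function(x) x@meta)

#' @rdname barcodeSeqs
#' @export
setMethod("speciesLabels", "BarcodeDataset", function(x)
  stats::setNames(as.character(x@meta$species), x@meta$id))

#' @rdname barcodeSeqs
#' @export
setMethod("speciesLabels", "K2PDistanceMatrix", function(x) x@species)

#' @export
setMethod("length", "BarcodeDataset", function(x) length(x@seqs))

#' @export
setMethod("names", "BarcodeDataset", function(x) names(x@seqs))

#' @export
setMethod("[", "BarcodeDataset", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@meta$id)
  initialize(x, seqs = x@seqs[i], meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "BarcodeDataset", function(object) {
  cat(class(object), "with", length(object@seqs), "records,",
      length(unique(object@meta$species)), "species\n")
  if (is(object, "BarcodeAlignment") && length(object@seqs))
    cat("  aligned length:", Biostrings::width(object@seqs)[1L],
        "columns\n")
  loci <- unique(object@meta$locus)
  loci <- loci[nzchar(loci)]
  if (length(loci)) cat("  locus:", paste(loci, collapse = ", "), "\n")
})

#' Apply the sampling screen to a dataset
#'
#' Keeps records whose non-gap length exceeds `minLength` and (when
#' `requireVoucher`) whose individual/voucher field is non-empty —
#' operationalising the "appropriate voucher, more than 300 bp" screen
#' used when assembling barcode reference sets. The length bound is a
#' strict inequality: a 300 bp record is rejected under the default.
#'
#' @param x A `BarcodeDataset`.
#' @param minLength Records must have non-gap length strictly greater
#'   than this (default 300).
#' @param requireVoucher Reject records with an empty individual field.
#' @return A list with `kept` (a `BarcodeDataset`) and `rejected`
#'   (a `data.frame` with columns `id`, `reason`; reasons are
#'   `"length"`, `"no_voucher"`, or both joined by `";"`).
#' @export
filterRecords <- function(x, minLength = 300, requireVoucher = TRUE) {
  stopifnot(is(x, "BarcodeDataset"))
  if (length(x) == 0L)
    return(list(kept = x,
                rejected = data.frame(id = character(),
                                      reason = character())))
  nongap <- Biostrings::width(x@seqs) -
    as.integer(Biostrings::letterFrequency(x@seqs, "-"))
  shortSeq <- nongap <= minLength
  noVoucher <- requireVoucher & !nzchar(x@meta$individual)
  drop <- shortSeq | noVoucher
  reason <- character(sum(drop))
  reason <- paste0(ifelse(shortSeq[drop], "length", ""),
                   ifelse(shortSeq[drop] & noVoucher[drop], ";", ""),
                   ifelse(noVoucher[drop], "no_voucher", ""))
  list(kept = x[!drop],
       rejected = data.frame(id = as.character(x@meta$id[drop]),
                             reason = reason))
}

#' Species/individual bookkeeping for a dataset
#'
#' @param x A `BarcodeDataset`.
#' @return A list with `nSpecies`, `nIndividuals` (= number of records,
#'   the "species samples (individuals)" convention) and
#'   `perSpeciesCounts`, a named integer vector.
#' @rdname datasetSummary
#' @export
setMethod("datasetSummary", "BarcodeDataset", function(x) {
  counts <- table(as.character(x@meta$species))
  counts <- counts[counts > 0L]
  perSpecies <- stats::setNames(as.integer(counts), names(counts))
  list(nSpecies = length(perSpecies),
       nIndividuals = length(x),
       perSpeciesCounts = perSpecies)
})
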