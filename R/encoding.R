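#' Parse a peptide token string
#'
#' Two dialects are accepted. In the compact dialect every letter is one
#' residue and every maximal run of digits is one numeric non-natural residue
#' ID ("TLTRV108W" -> T, L, T, R, V, 108, W). In the hyphen-separated dialect
#' tokens are split on "-" ("512-439" -> 512, 439) and each segment may itself
#' be compact. Natural one-letter codes are case-insensitive and normalized to
#' uppercase; order is N-terminus first.
#'
#' @param text Non-empty sequence string.
#' @return Character vector of residue tokens, N to C.
#' @examples
#' parseSequence("TLTRV108W")
#' parseSequence("512-439")
#' @export
parseSequence <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("sequence string must be a single non-empty string")
  segments <- if (grepl("-", text, fixed = TRUE)) {
    strsplit(text, "-", fixed = TRUE)[[1]]
  } else text
  if (any(!nzchar(segments)))
    stop("empty token between hyphens in sequence '", text, "'")
  tokens <- character(0)
  for (seg in segments) {
    chars <- strsplit(seg, "")[[1]]
    bad <- which(!grepl("^[A-Za-z0-9]$", chars))
    if (length(bad))
      stop(sprintf("invalid character '%s' at position %d of segment '%s'",
                   chars[bad[1]], bad[1], seg))
    # maximal digit runs become one numeric token; letters are single tokens
    pieces <- regmatches(seg, gregexpr("[0-9]+|[A-Za-z]", seg))[[1]]
    tokens <- c(tokens, toupper(pieces))
  }
  tokens
}

#' Format tokens back into a canonical sequence string
#'
#' Canonical form is hyphen-separated whenever any token is numeric, compact
#' otherwise, so `formatSequence(parseSequence(s))` is a stable canonical form.
#'
#' @param tokens Character vector of residue tokens.
#' @return Single string.
#' @export
formatSequence <- function(tokens) {
  if (any(grepl("^[0-9]+$", tokens)))
    paste(tokens, collapse = "-")
  else paste(tokens, collapse = "")
}

.lookupTokens <- function(tokens, scales) {
  s <- scoreMatrix(scales)
  hit <- match(tokens, rownames(s))
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1]
    stop(sprintf("unknown residue token '%s' at position %d", tokens[i], i))
  }
  s[hit, , drop = FALSE]
}

#' Encode one peptide as positional factor-score descriptors
#'
#' Concatenates the factor-score vector of each residue position-major:
#' pos1.f1 .. pos1.fm, pos2.f1 .. The descriptor length is m times the
#' peptide length.
#'
#' @param peptide Sequence string or token vector.
#' @param scales A [ScaleTable-class].
#' @return Named numeric vector of length m * L.
#' @export
encodePeptide <- function(peptide, scales) {
  tokens <- if (length(peptide) == 1L && !is.numeric(peptide))
    parseSequence(peptide) else as.character(peptide)
  sc <- .lookupTokens(tokens, scales)
  v <- as.vector(t(sc))
  names(v) <- paste0("pos", rep(seq_along(tokens), each = ncol(sc)),
                     ".", rep(colnames(sc), length(tokens)))
  v
}

#' Encode a set of equal-length peptides as a descriptor matrix
#'
#' @param sequences Character vector of sequence strings (or list of token
#'   vectors); all peptides must have the same length.
#' @param scales A [ScaleTable-class].
#' @param ids Optional sample IDs (default: names of `sequences` or 1..n).
#' @return Numeric matrix, samples x (m * L), with `pos{i}.{factor}` column
#'   names and sample IDs as rownames.
#' @export
encodeDataset <- function(sequences, scales, ids = NULL) {
  if (length(sequences) == 0L) stop("no peptides to encode")
  tokenList <- if (is.list(sequences)) lapply(sequences, as.character)
               else lapply(sequences, parseSequence)
  if (is.null(ids)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- as.character(seq_along(tokenList))
  }
  lens <- lengths(tokenList)
  if (length(unique(lens)) != 1L)
    stop("peptides must all have the same length; offending samples: ",
         paste(ids[lens != lens[1]], collapse = ", "))
  rows <- lapply(tokenList, encodePeptide, scales = scales)
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  X
}
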