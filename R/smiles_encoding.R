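## Character-level one-hot encoding of canonical SMILES with start/end/pad
## special tokens and a fixed maximum length of 120 positions.

SMILES_START <- "^"
SMILES_END <- "$"
SMILES_PAD <- " "

#' Build a SMILES character dictionary from a corpus
#'
#' The vocabulary is the set of characters observed in the corpus plus the
#' three special tokens (start, end, pad), in a fixed order: pad, start,
#' end, then sorted characters.  In production (trained on the full profile
#' corpus) this dictionary has 47 entries; the size is logged, not forced.
#'
#' @param smiles Character vector of SMILES (the training corpus).
#' @return Object of class `smiles_dictionary`: character vector with
#'   attributes.
#' @export
build_smiles_dictionary <- function(smiles) {
  chars <- sort(unique(unlist(strsplit(smiles, "", fixed = TRUE))))
  chars <- setdiff(chars, c(SMILES_PAD, SMILES_START, SMILES_END))
  dict <- c(SMILES_PAD, SMILES_START, SMILES_END, chars)
  structure(dict, class = "smiles_dictionary")
}

#' @export
print.smiles_dictionary <- function(x, ...) {
  cat("SMILES dictionary:", length(x), "characters (3 special tokens)\n")
  invisible(x)
}

#' Persist / load a SMILES dictionary as JSON
#'
#' @param dict A `smiles_dictionary`.
#' @param path JSON file path.
#' @export
write_smiles_dictionary <- function(dict, path) {
  jsonlite::write_json(unclass(dict), path)
  invisible(path)
}

#' @rdname write_smiles_dictionary
#' @export
read_smiles_dictionary <- function(path) {
  dict <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  if (!identical(dict[1:3], c(SMILES_PAD, SMILES_START, SMILES_END))) {
    stop_digera("corrupt SMILES dictionary: special tokens missing",
                class = "digera_validation_error")
  }
  structure(dict, class = "smiles_dictionary")
}

#' One-hot encode a SMILES string
#'
#' Produces a `max_len x |dictionary|` binary matrix: start token, one row
#' per character, end token, then pad rows.  Molecules whose SMILES exceeds
#' `max_len - 2` characters or whose molecular weight exceeds `max_mw` are
#' rejected (the production corpus filters them out with a logged reason).
#'
#' @param smiles A single SMILES string.
#' @param dict A [build_smiles_dictionary()] result.
#' @param max_len Total encoded length including specials (default 120).
#' @param max_mw Molecular-weight cap (default 600); `Inf` disables the
#'   check (and the chemistry round trip).
#' @return Object of class `smiles_encoding`: binary matrix with the
#'   dictionary as an attribute.
#' @export
smiles_one_hot <- function(smiles, dict, max_len = 120L, max_mw = 600) {
  stopifnot(length(smiles) == 1L, inherits(dict, "smiles_dictionary"))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (length(chars) > max_len - 2L) {
    stop_digera("SMILES has ", length(chars), " tokens; limit is ",
                max_len - 2L, class = "digera_validation_error")
  }
  if (is.finite(max_mw)) {
    props <- mol_properties(smiles)
    if (!props$valid[1]) {
      stop_digera("unparseable SMILES: ", smiles,
                  class = "digera_featurization_error")
    }
    if (props$mw[1] > max_mw) {
      stop_digera("molecular weight ", round(props$mw[1], 1),
                  " exceeds the encoding cap ", max_mw,
                  class = "digera_validation_error")
    }
  }
  unknown <- setdiff(chars, dict)
  if (length(unknown)) {
    stop_digera("characters outside the dictionary: ",
                paste(sQuote(unknown), collapse = ", "),
                class = "digera_encoding_error")
  }
  tokens <- c(SMILES_START, chars, SMILES_END,
              rep(SMILES_PAD, max_len - length(chars) - 2L))
  m <- matrix(0L, nrow = max_len, ncol = length(dict),
              dimnames = list(NULL, dict))
  m[cbind(seq_len(max_len), match(tokens, dict))] <- 1L
  structure(m, class = c("smiles_encoding", "matrix"), dictionary = dict)
}

#' Decode a one-hot SMILES encoding back to the string
#'
#' @param encoding A [smiles_one_hot()] matrix.
#' @return The SMILES string (specials stripped).
#' @export
smiles_decode <- function(encoding) {
  dict <- attr(encoding, "dictionary")
  tokens <- dict[max.col(encoding)]
  tokens <- tokens[!(tokens %in% c(SMILES_PAD, SMILES_START, SMILES_END))]
  paste(tokens, collapse = "")
}
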