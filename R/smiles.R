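# SMILES validation and canonicalization backend (OpenBabel via ChemmineOB).
#
# OpenBabel is permissive with malformed SMILES (it silently truncates "C("
# to "C"), so a lexical validity check runs before any conversion. The check
# is purely syntactic: token legality, balanced parentheses and brackets,
# paired ring-bond digits. Semantic validity (valence etc.) is left to the
# backend.

# organic-subset atoms writable without brackets
.smiles_organic <- c(
  "Br", "Cl", "B", "C", "N", "O", "P", "S", "F", "I",
  "b", "c", "n", "o", "p", "s"
)

#' Check whether a string is lexically valid SMILES
#'
#' A light syntactic screen: legal tokens only, balanced `()` and `[]`,
#' every ring-closure digit opened and closed, no empty branches, and the
#' string neither starts nor ends with a bond token. It deliberately does
#' not check valence; that is the chemistry backend's job.
#'
#' @param smiles Character scalar.
#' @return `TRUE` or `FALSE`.
#' @keywords internal
smiles_is_valid <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  depth <- 0L
  ring <- integer(0)          # open ring-bond ids
  prev_atom <- FALSE          # last token completed an atom
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n || j == i + 1L) return(FALSE)        # unclosed or empty
      body <- substr(smiles, i + 1L, j - 1L)
      if (!grepl("^[-A-Za-z0-9@+*]+$", body)) return(FALSE)
      prev_atom <- TRUE
      i <- j + 1L
      next
    }
    if (ch == "(") {
      if (!prev_atom) return(FALSE)                  # branch needs an atom
      depth <- depth + 1L
      prev_atom <- FALSE
      i <- i + 1L
      next
    }
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
      if (i > 1L && chars[i - 1L] == "(") return(FALSE)   # empty branch
      prev_atom <- TRUE
      i <- i + 1L
      next
    }
    if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
          return(FALSE)
        }
        id <- as.integer(substr(smiles, i + 1L, i + 2L))
        i <- i + 3L
      } else {
        id <- as.integer(ch)
        i <- i + 1L
      }
      if (!prev_atom) return(FALSE)                  # ring bond needs an atom
      if (id %in% ring) ring <- setdiff(ring, id) else ring <- c(ring, id)
      next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\", "~", "$")) {
      prev_atom <- FALSE
      i <- i + 1L
      next
    }
    if (ch == ".") {
      if (i == 1L || i == n) return(FALSE)
      prev_atom <- FALSE
      i <- i + 1L
      next
    }
    # two-letter then one-letter organic atoms
    two <- if (i < n) substr(smiles, i, i + 1L) else ""
    if (two %in% .smiles_organic) {
      prev_atom <- TRUE
      i <- i + 2L
      next
    }
    if (ch %in% .smiles_organic) {
      prev_atom <- TRUE
      i <- i + 1L
      next
    }
    return(FALSE)
  }
  depth == 0L && length(ring) == 0L && prev_atom
}

# session-lifetime memo caches keyed by input string
.synkit_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!is.null(.synkit_cache[[key]])) {
    return(.synkit_cache[[key]])
  }
  val <- compute()
  .synkit_cache[[key]] <- val
  val
}

ob_convert <- function(smiles, to) {
  out <- ChemmineOB::convertFormat("SMI", to, source = smiles)
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  vapply(out, function(x) strsplit(x, "\t", fixed = TRUE)[[1]][1], "",
         USE.NAMES = FALSE)
}

#' Canonical SMILES of a single structure (cached)
#' @keywords internal
ob_canonical_smiles <- function(smiles) {
  cache_get_or(paste0("can\r", smiles), function() {
    out <- ob_convert(smiles, "CAN")
    if (length(out) != 1L || is.na(out[1]) || !nzchar(out[1])) {
      stop_synkit("invalid_structure",
                  "structure could not be canonicalized: '", smiles, "'")
    }
    out[1]
  })
}

#' InChIKey of a single structure (cached)
#' @keywords internal
ob_inchikey <- function(smiles) {
  cache_get_or(paste0("ikey\r", smiles), function() {
    out <- suppressWarnings(ob_convert(smiles, "INCHIKEY"))
    if (length(out) != 1L || is.na(out[1]) || !nzchar(out[1])) {
      stop_synkit("invalid_structure",
                  "no InChIKey could be derived for: '", smiles, "'")
    }
    out[1]
  })
}

# Remove stereochemical tokens (tetrahedral @ marks, cis/trans slashes)
# before canonicalization; equivalent to the backend's no-stereo output.
strip_stereo <- function(smiles) {
  gsub("[/\\\\]", "", gsub("@", "", smiles, fixed = TRUE))
}

# condition helper used across the package
stop_synkit <- function(class, ..., call = NULL) {
  msg <- paste0(...)
  cnd <- structure(
    class = c(paste0("synkit_", class), "synkit_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cnd)
}
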