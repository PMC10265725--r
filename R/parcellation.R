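#' AAL-90 region labels
#'
#' Region labels for the 90-region Automated Anatomical Labeling parcellation
#' (cerebrum only), in standard atlas order: homologous left/right pairs
#' alternate, odd indices are left-hemisphere, even indices right.
#'
#' @return Character vector of length 90, e.g. `"PreCG.L"`, `"PreCG.R"`, ...
#' @export
aal90_labels <- function() {
  stems <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(stems, ".L"), paste0(stems, ".R")))
}

#' Hemisphere of each parcellation node
#'
#' Follows the AAL ordering convention: odd 1-based node index = left
#' hemisphere, even = right.
#'
#' @param n_nodes Number of nodes (default 90).
#' @return Character vector of `"L"`/`"R"` per node.
#' @export
aal90_hemispheres <- function(n_nodes = 90L) {
  ifelse(seq_len(n_nodes) %% 2L == 1L, "L", "R")
}

#' Homologous region pair stem for each node
#'
#' Strips the hemisphere suffix so left/right homologues share a label; used
#' to build nodal model frames with a hemisphere covariate.
#'
#' @param labels Node labels as produced by [aal90_labels()].
#' @return Character vector of region stems (45 unique values for AAL-90).
#' @export
region_stems <- function(labels = aal90_labels()) {
  sub("\\.(L|R)$", "", labels)
}

# Deterministic sub-seed derivation: one global seed fans out to per-stage,
# per-scan streams. Constants give good dispersion over 32-bit range.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    s <- (s * 48271 + kk * 16807 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483562 + 1)
}
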