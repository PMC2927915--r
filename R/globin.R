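## Residue charge classes at pH 7. Histidine is counted neutral: its
## imidazole pKa (~6) sits below physiological pH and its context-dependence
## is not modelled here.
NEGATIVE_AA <- c("D", "E")
POSITIVE_AA <- c("K", "R")

aa_charge <- function(aa) {
  dplyr::case_when(
    aa %in% NEGATIVE_AA ~ "negative",
    aa %in% POSITIVE_AA ~ "positive",
    TRUE ~ "neutral"
  )
}

classify_charge_change <- function(ref_aa, query_aa) {
  from <- aa_charge(ref_aa)
  to <- aa_charge(query_aa)
  dplyr::case_when(
    from == to ~ "none",
    from == "neutral" & to == "negative" ~ "gain_negative",
    from == "neutral" & to == "positive" ~ "gain_positive",
    from == "negative" & to == "neutral" ~ "loss_negative",
    from == "positive" & to == "neutral" ~ "loss_positive",
    TRUE ~ "swap" # positive <-> negative
  )
}

#' Read globin chains from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning the tibble
#' layout the audit functions consume. Sequences are expected as mature
#' chains (initiator Met removed), numbered from 1 at the N-terminal residue;
#' `trim_initiator_met = TRUE` drops a leading Met for cDNA-derived input.
#'
#' @param path Path to a FASTA file of amino-acid sequences (aligned or
#'   equal-length; gaps `-` allowed).
#' @param trim_initiator_met Drop a leading "M" from every sequence.
#' @return A tibble with columns `id`, `residues` (upper-case one-letter
#'   strings).
#' @export
read_globin_fasta <- function(path, trim_initiator_met = FALSE) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_globin_fasta() needs the Biostrings package.")
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa)) # first header token, as usual
  res <- toupper(as.character(aa))
  if (trim_initiator_met) {
    res <- ifelse(startsWith(res, "M"), substring(res, 2), res)
  }
  tibble::tibble(id = ids, residues = unname(res))
}

#' List amino-acid substitutions between two aligned chains
#'
#' Compares a query chain against a reference position by position (mature
#' numbering: position 1 is the N-terminal residue) and reports every
#' differing non-gap column together with its charge-change class at pH 7:
#' `{D, E}` negative, `{K, R}` positive, everything else (including His)
#' neutral. Gap columns are skipped, not reported.
#'
#' @param query,reference Amino-acid strings of equal length (one-letter
#'   code, `-` for gaps).
#' @return A tibble with columns `position`, `ref_aa`, `query_aa`,
#'   `charge_change` (one of `none`, `gain_negative`, `gain_positive`,
#'   `loss_negative`, `loss_positive`, `swap`).
#' @examples
#' list_substitutions("VHLE", "VHLG") # 4: G -> E, gain_negative
#' @export
list_substitutions <- function(query, reference) {
  stopifnot(is.character(query), is.character(reference),
            length(query) == 1L, length(reference) == 1L)
  if (nchar(query) != nchar(reference)) {
    abort("length mismatch: query and reference must be aligned to equal length")
  }
  q <- strsplit(toupper(query), "")[[1]]
  r <- strsplit(toupper(reference), "")[[1]]
  diff <- which(q != r & q != "-" & r != "-")
  tibble::tibble(
    position = diff,
    ref_aa = r[diff],
    query_aa = q[diff],
    charge_change = classify_charge_change(r[diff], q[diff])
  )
}

## Canonical DPG-binding residues of beta-type chains, mature numbering.
DPG_SITES <- c(`1` = "V", `2` = "H", `82` = "K", `143` = "H")

#' Audit the canonical DPG-binding residues of a beta-type chain
#'
#' Checks the cationic-pocket positions of beta-type globins — 1 (Val),
#' 2 (His), 82 (Lys) and 143 (His) in mature numbering — and reports whether
#' each is conserved or substituted. A chain can be fully conserved at these
#' sites yet DPG-insensitive for other structural reasons, which is exactly
#' what this audit is designed to surface alongside [list_substitutions()].
#'
#' @param chain Amino-acid string of a mature beta-type chain (length >=
#'   143).
#' @return A tibble with columns `position`, `expected`, `observed`,
#'   `status` (`"conserved"` / `"substituted"`), carrying an
#'   `all_conserved` attribute (logical).
#' @examples
#' aud <- dpg_site_audit(strrep("A", 143))
#' attr(aud, "all_conserved")
#' @export
dpg_site_audit <- function(chain) {
  stopifnot(is.character(chain), length(chain) == 1L)
  if (nchar(chain) < 143) {
    abort("chain shorter than 143 residues: cannot audit DPG-binding sites")
  }
  pos <- as.integer(names(DPG_SITES))
  obs <- substring(toupper(chain), pos, pos)
  out <- tibble::tibble(
    position = pos,
    expected = unname(DPG_SITES),
    observed = obs,
    status = unname(ifelse(obs == DPG_SITES, "conserved", "substituted"))
  )
  attr(out, "all_conserved") <- all(out$status == "conserved")
  out
}
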