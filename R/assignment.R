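# Matching deconvoluted neutral masses to the proteoform target table:
# modification enumeration, accurate-mass matching, and unexplained-shift
# flagging (e.g. a +29 Da variant satellite).

# enumerate allowed modification states of one target
.mod_states <- function(spec, max_oxidation = 2, max_acetyl = 1) {
  nphos_base <- if ("phospho" %in% names(spec$modifications))
    spec$modifications[["phospho"]] else 0L
  phos_room <- max(spec$phospho_sites_max - nphos_base, 0L)
  states <- expand.grid(phospho = 0:phos_room, oxidation = 0:max_oxidation,
                        acetyl = 0:max_acetyl)
  states$mass <- proteoform_mass(spec) +
    states$phospho * .const$mod_deltas[["phospho"]] +
    states$oxidation * .const$mod_deltas[["oxidation"]] +
    states$acetyl * .const$mod_deltas[["acetyl"]]
  states$n_mods <- states$phospho + states$oxidation + states$acetyl
  states$n_phospho_total <- states$phospho + nphos_base
  states
}

.mod_label <- function(phospho, oxidation, acetyl) {
  parts <- character(0)
  if (phospho > 0) parts <- c(parts, sprintf("%dP", phospho))
  if (oxidation > 0) parts <- c(parts, sprintf("%dox", oxidation))
  if (acetyl > 0) parts <- c(parts, sprintf("%dac", acetyl))
  if (!length(parts)) "" else paste0("+", paste(parts, collapse = "+"))
}

#' Assign deconvoluted peaks to proteoform targets
#'
#' For every peak, all target base masses plus allowed modification
#' combinations (phospho up to `phospho_sites_max`, up to `max_oxidation`
#' oxidations and `max_acetyl` acetyls) are enumerated; the best match is the
#' candidate with the smallest absolute ppm error within `ppm_tol`, ties
#' broken by fewest total modifications then lexicographic proteoform id.
#' A peak matching no candidate but lying within `max_unknown_shift` Da of
#' some target's proteoform series is reported as `shifted` with the shift
#' rounded to 0.1 Da (never silently absorbed into the ppm error); anything
#' else is `unassigned`.
#'
#' @param decon A `deconvoluted_spectrum`.
#' @param targets A `target_table` (or list of [proteoform_spec()]).
#' @param ppm_tol Match tolerance in ppm (default 10).
#' @param max_unknown_shift Largest unexplained shift to flag, Da (default
#'   100).
#' @param max_oxidation,max_acetyl Modification enumeration caps.
#' @return Data frame of class `assignment_table`: one row per peak with
#'   `neutral_mass`, `intensity`, `proteoform_id`, `protein_name`, `label`,
#'   `mods`, `n_phospho`, `ppm`, `status` (`matched`/`shifted`/`unassigned`),
#'   `shift_da`, and a `charges` list column.
#' @export
assign_peaks <- function(decon, targets, ppm_tol = 10,
                         max_unknown_shift = 100,
                         max_oxidation = 2, max_acetyl = 1) {
  if (!length(targets)) stop("targets must be non-empty")
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  cand <- do.call(rbind, lapply(targets, function(sp) {
    st <- .mod_states(sp, max_oxidation, max_acetyl)
    st$id <- sp$id
    st$protein <- sp$protein_name
    st
  }))
  n <- nrow(decon)
  out <- data.frame(
    neutral_mass = numeric(n), intensity = numeric(n),
    proteoform_id = NA_character_, protein_name = NA_character_,
    label = NA_character_, mods = NA_character_, n_phospho = NA_integer_,
    ppm = NA_real_, status = character(n), shift_da = NA_real_,
    stringsAsFactors = FALSE
  )
  out$charges <- vector("list", n)
  for (i in seq_len(n)) {
    m <- decon$neutral_mass[i]
    out$neutral_mass[i] <- m
    out$intensity[i] <- decon$intensity[i]
    out$charges[[i]] <- decon$charges[[i]]
    pp <- ppm_error(m, cand$mass)
    ok <- abs(pp) <= ppm_tol
    if (any(ok)) {
      sub <- cand[ok, ]
      sub$app <- abs(pp[ok])
      sub <- sub[order(sub$app, sub$n_mods, sub$id), ]
      b <- sub[1, ]
      lab <- .mod_label(b$phospho, b$oxidation, b$acetyl)
      out$proteoform_id[i] <- b$id
      out$protein_name[i] <- b$protein
      out$label[i] <- paste0(b$id, lab)
      out$mods[i] <- lab
      out$n_phospho[i] <- as.integer(b$n_phospho_total)
      out$ppm[i] <- ppm_error(m, b$mass)
      out$status[i] <- "matched"
    } else {
      d <- m - cand$mass
      j <- which.min(abs(d))
      if (abs(d[j]) <= max_unknown_shift) {
        # shift reported relative to the target's base (unmodified) state,
        # the convention used when flagging variant satellites
        base_j <- which(cand$id == cand$id[j] & cand$n_mods == 0)[1]
        shift <- round(m - cand$mass[base_j], 1)
        out$proteoform_id[i] <- cand$id[j]
        out$protein_name[i] <- cand$protein[j]
        out$label[i] <- sprintf("%s%+.1fDa", cand$id[j], shift)
        out$mods[i] <- ""
        out$n_phospho[i] <- as.integer(cand$n_phospho_total[cand$id == cand$id[j] &
                                                              cand$n_mods == 0][1])
        out$ppm[i] <- NA_real_
        out$status[i] <- "shifted"
        out$shift_da[i] <- shift
      } else {
        out$status[i] <- "unassigned"
      }
    }
  }
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Proteoform series of one protein
#'
#' All matched and shifted assignments of a protein, ordered by mass, with
#' intensities carried from the deconvoluted peaks — the protein's
#' phospho/modification series used for relative quantification.
#'
#' @param assignments An `assignment_table` from [assign_peaks()].
#' @param protein_name Protein to extract.
#' @param targets The target table the assignments were made against (used to
#'   validate the protein name).
#' @return Data frame subset of `assignments` sorted by mass (possibly zero
#'   rows if the protein was not detected).
#' @export
proteoform_series <- function(assignments, protein_name, targets = NULL) {
  if (!is.null(targets)) {
    known <- vapply(targets, `[[`, character(1), "protein_name")
    if (!protein_name %in% known)
      stop("protein not in target table: ", protein_name)
  }
  sel <- assignments$status %in% c("matched", "shifted") &
    assignments$protein_name == protein_name
  sel[is.na(sel)] <- FALSE
  out <- assignments[sel, , drop = FALSE]
  out <- out[order(out$neutral_mass), , drop = FALSE]
  if (anyDuplicated(out$label)) {
    # keep the most intense peak per proteoform label
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$label),
                          function(ix) ix[which.max(out$intensity[ix])]))
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write an assignment table as CSV
#' @param assignments An `assignment_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignment_csv <- function(assignments, path) {
  df <- assignments
  df$charges <- vapply(df$charges, function(z) paste(z, collapse = ";"),
                       character(1))
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
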