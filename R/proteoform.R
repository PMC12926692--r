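# Proteoform target specifications and the TSV target-table interface.

#' Define a proteoform target
#'
#' A proteoform is a specific intact molecular form of a protein: a base
#' (unmodified) monoisotopic mass plus a defined modification state. Targets
#' are matched against deconvoluted neutral masses by [assign_peaks()].
#'
#' @param id Short unique identifier (e.g. `"MLC2S"`).
#' @param protein_name Protein isoform name (e.g. `"MLC2S"`).
#' @param gene Gene symbol (e.g. `"MYL2"`).
#' @param base_neutral_mass Monoisotopic mass of the unmodified proteoform, Da.
#' @param modifications Named integer vector of baseline modification counts,
#'   e.g. `c(phospho = 1)`. Names must be known to `mass_constants()$mod_deltas`.
#' @param phospho_sites_max Maximum number of phosphorylatable sites.
#' @return Object of class `proteoform_spec`.
#' @examples
#' proteoform_spec("aTpm", "aTpm", "TPM1", 32680, phospho_sites_max = 2)
#' @export
proteoform_spec <- function(id, protein_name, gene, base_neutral_mass,
                            modifications = integer(), phospho_sites_max = 0L) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (base_neutral_mass <= 0) stop("base_neutral_mass must be positive")
  if (phospho_sites_max < 0) stop("phospho_sites_max must be non-negative")
  modifications <- .as_mod_counts(modifications)
  unknown <- setdiff(names(modifications), names(.const$mod_deltas))
  if (length(unknown))
    stop("unknown modification(s): ", paste(unknown, collapse = ", "))
  nphos <- if ("phospho" %in% names(modifications)) modifications[["phospho"]] else 0L
  if (nphos > phospho_sites_max)
    stop("phospho count exceeds phospho_sites_max for ", id)
  structure(list(id = id, protein_name = protein_name, gene = gene,
                 base_neutral_mass = base_neutral_mass,
                 modifications = modifications,
                 phospho_sites_max = as.integer(phospho_sites_max)),
            class = "proteoform_spec")
}

.as_mod_counts <- function(x) {
  if (is.null(x) || length(x) == 0) return(integer())
  if (is.list(x)) {  # list of (name, count) pairs
    nm <- vapply(x, function(p) as.character(p[[1]]), character(1))
    ct <- vapply(x, function(p) as.integer(p[[2]]), integer(1))
    x <- stats::setNames(ct, nm)
  }
  x <- x[x != 0]
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("modifications must be named counts")
  storage.mode(x) <- "integer"
  x
}

#' Monoisotopic mass of a proteoform
#'
#' Base neutral mass plus the summed modification deltas.
#'
#' @param spec A `proteoform_spec`, or a numeric base mass.
#' @param modifications Named counts of additional modifications to add on top
#'   of `spec`'s own (default none).
#' @return Mass in Da.
#' @examples
#' proteoform_mass(10000, c(phospho = 1))
#' @export
proteoform_mass <- function(spec, modifications = integer()) {
  extra <- .as_mod_counts(modifications)
  if (inherits(spec, "proteoform_spec")) {
    base <- spec$base_neutral_mass
    mods <- spec$modifications
  } else {
    stopifnot(is.numeric(spec), length(spec) == 1)
    base <- spec
    mods <- integer()
  }
  all_mods <- c(mods, extra)
  if (!length(all_mods)) return(base)
  unknown <- setdiff(names(all_mods), names(.const$mod_deltas))
  if (length(unknown))
    stop("unknown modification(s): ", paste(unknown, collapse = ", "))
  base + sum(all_mods * .const$mod_deltas[names(all_mods)])
}

.mods_to_string <- function(mods) {
  if (!length(mods)) return("")
  paste(sprintf("%s:%d", names(mods), mods), collapse = ";")
}

.mods_from_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.integer(p[2]), integer(1)),
                  vapply(kv, `[`, character(1), 1))
}

#' Read a proteoform target table
#'
#' Tab-separated file with columns `id`, `protein_name`, `gene`,
#' `base_neutral_mass_da`, `modifications` (semicolon list `"name:count"`,
#' empty allowed), `phospho_sites_max`.
#'
#' @param path Path to the TSV file.
#' @return List of `proteoform_spec` objects (class `target_table`).
#' @export
read_target_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "protein_name", "gene", "base_neutral_mass_da",
                "modifications", "phospho_sites_max")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("target table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate proteoform id in target table")
  specs <- lapply(seq_len(nrow(df)), function(i)
    proteoform_spec(df$id[i], df$protein_name[i], df$gene[i],
                    df$base_neutral_mass_da[i],
                    .mods_from_string(as.character(df$modifications[i])),
                    df$phospho_sites_max[i]))
  structure(specs, class = "target_table")
}

#' Write a proteoform target table
#'
#' @param targets List of `proteoform_spec` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(targets, path) {
  df <- as.data.frame(targets)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.target_table <- function(x, ...) {
  data.frame(
    id = vapply(x, `[[`, character(1), "id"),
    protein_name = vapply(x, `[[`, character(1), "protein_name"),
    gene = vapply(x, `[[`, character(1), "gene"),
    base_neutral_mass_da = vapply(x, `[[`, numeric(1), "base_neutral_mass"),
    modifications = vapply(x, function(s) .mods_to_string(s$modifications),
                           character(1)),
    phospho_sites_max = vapply(x, `[[`, integer(1), "phospho_sites_max"),
    stringsAsFactors = FALSE
  )
}

#' Coerce a list of proteoform specs to a target table
#' @param specs List of `proteoform_spec` objects.
#' @return `target_table` object.
#' @export
target_table <- function(specs) {
  stopifnot(all(vapply(specs, inherits, logical(1), "proteoform_spec")))
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate proteoform id")
  structure(specs, class = "target_table")
}
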