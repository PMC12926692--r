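# mzML 1.1.0 input/output. Reading goes through mzR (proteowizard backend);
# writing uses a minimal deterministic writer so that identical runs produce
# byte-identical files.

.b64_doubles <- function(x, size) {
  if (!length(x)) return("")
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = size,
                                                   endian = "little")))
}

.xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Write a run to mzML
#'
#' Emits schema-conformant mzML 1.1.0 with MS1 spectra, retention times in
#' minutes, 64-bit m/z and 32-bit intensity arrays (uncompressed, little
#' endian). The writer is deterministic: identical runs yield byte-identical
#' files.
#'
#' @param run A `spectrum_run`.
#' @param path Output path (conventionally `.mzML`).
#' @return `path`, invisibly.
#' @seealso [read_mzml()]
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "spectrum_run"))
  mode_cv <- if (run$mode == "centroid")
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>'
  n <- n_scans(run)
  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="utf-8"?>')
  add('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="fiberform_run">')
  add('  <cvList count="2">')
  add('    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
  add('    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>')
  add('  </cvList>')
  add('  <fileDescription>')
  add('    <fileContent>')
  add('      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
  add('      ', mode_cv)
  add('    </fileContent>')
  add('  </fileDescription>')
  add('  <softwareList count="1">')
  add('    <software id="fiberform" version="0.1.0">')
  add('      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="fiberform"/>')
  add('    </software>')
  add('  </softwareList>')
  add('  <instrumentConfigurationList count="1">')
  add('    <instrumentConfiguration id="IC1">')
  add('      <cvParam cvRef="MS" accession="MS:1000188" name="Q-Tof micro" value=""/>')
  add('    </instrumentConfiguration>')
  add('  </instrumentConfigurationList>')
  add('  <dataProcessingList count="1">')
  add('    <dataProcessing id="dp1">')
  add('      <processingMethod order="1" softwareRef="fiberform">')
  add('        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>')
  add('      </processingMethod>')
  add('    </dataProcessing>')
  add('  </dataProcessingList>')
  add('  <run id="run1" defaultInstrumentConfigurationRef="IC1">')
  add(sprintf('    <spectrumList count="%d" defaultDataProcessingRef="dp1">', n))
  for (i in seq_len(n)) {
    s <- run$scans[[i]]
    np <- length(s$mz)
    mz64 <- .b64_doubles(s$mz, 8L)
    it32 <- .b64_doubles(s$intensity, 4L)
    add(sprintf('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
                i - 1L, i, np))
    add('        <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>')
    add('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>')
    add('        ', mode_cv)
    add('        <scanList count="1">')
    add('          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>')
    add('          <scan>')
    add(sprintf('            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.8f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>',
                s$rt))
    add('          </scan>')
    add('        </scanList>')
    add('        <binaryDataArrayList count="2">')
    add(sprintf('          <binaryDataArray encodedLength="%d">', nchar(mz64)))
    add('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
    add('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    add('            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
    add('            <binary>', mz64, '</binary>')
    add('          </binaryDataArray>')
    add(sprintf('          <binaryDataArray encodedLength="%d">', nchar(it32)))
    add('            <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>')
    add('            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
    add('            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
    add('            <binary>', it32, '</binary>')
    add('          </binaryDataArray>')
    add('        </binaryDataArrayList>')
    add('      </spectrum>')
  }
  add('    </spectrumList>')
  add('  </run>')
  add('</mzML>')
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an mzML file
#'
#' Parses MS1 spectra through `mzR` (proteowizard). Retention times are
#' converted to minutes. The centroid/profile flag is taken from the file's
#' CV params; when absent, the mode is inferred from peak density with a
#' warning.
#'
#' @param path Path to an mzML file.
#' @return A [spectrum_run()].
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ms <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(ms), add = TRUE)
  nh <- length(ms)
  if (nh == 0)
    return(spectrum_run(list(), mode = "centroid",
                        metadata = list(source = path)))
  hdr <- mzR::header(ms)
  pks <- mzR::peaks(ms)
  if (nh == 1) pks <- list(pks)
  centroided <- hdr$centroided
  if (all(is.na(centroided))) {
    # infer: centroid spectra have sparse, unevenly spaced peaks
    dens <- vapply(pks, function(p) {
      if (nrow(p) < 3) return(Inf)
      stats::median(diff(p[, 1]))
    }, numeric(1))
    mode <- if (stats::median(dens, na.rm = TRUE) > 0.02) "centroid" else "profile"
    warning("mzML lacks spectrum representation CV param; inferred mode '",
            mode, "' from peak density")
  } else {
    mode <- if (isTRUE(centroided[1])) "centroid" else "profile"
  }
  scans <- lapply(seq_len(nh), function(i) {
    p <- pks[[i]]
    list(rt = hdr$retentionTime[i] / 60, mz = as.numeric(p[, 1]),
         intensity = as.numeric(p[, 2]))
  })
  spectrum_run(scans, mode = mode, metadata = list(source = path))
}
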