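# Locator for the 290-isolate marine-fungal ITS reference alignments
# (CLUSTAL-O / KALIGN / MAFFT / MUSCLE outputs for the same 290 barcodes,
# GenBank KP890357-KP890646). These files are not redistributable with the
# package; to run the reference-data checks, download the published
# alignment files and place them under the directory given by
# options(barcodegap.supplementary_dir = ...) — default
# inst/extdata/supplementary — using the names below.
referenceAlignmentFile <- function(name) {
  dir <- getOption(
    "barcodegap.supplementary_dir",
    file.path(system.file("extdata", package = "barcodegap"),
              "supplementary"))
  file.path(dir, paste0(name, ".fasta"))
}

REFERENCE_ALIGNMENTS <- c(clustalo = "290_clustalo",
                          kalign = "290_kalign",
                          mafft = "290_mafft",
                          muscle = "290_muscle")

referenceDataAvailable <- function() {
  all(file.exists(vapply(REFERENCE_ALIGNMENTS, referenceAlignmentFile, "")))
}

missingReferenceDataMessage <- paste(
  "reference ITS alignment files are not bundled (they are not",
  "redistributable with the package); place the four 290-sequence",
  "alignment files under the directory configured via",
  "options(barcodegap.supplementary_dir=...) to run this check")
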