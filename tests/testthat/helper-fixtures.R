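# In-code fixtures: handwritten records and tiny labeled sets.

massbankRecord <- function(accession = "MSBNK-TEST-0001",
                           msType = "MS2", ionization = "ESI",
                           ionMode = "POSITIVE",
                           collisionEnergy = "35 eV",
                           inchikey = "VEQOALNAAJBPNY-UHFFFAOYSA-N",
                           smiles = "CC1=CC(=O)N(N1C)c1ccccc1",
                           peaks = list(c(146.05, 999), c(41.0, 12))) {
  c(paste0("ACCESSION: ", accession),
    "RECORD_TITLE: synthetic fixture",
    paste0("CH$SMILES: ", smiles),
    paste0("CH$LINK: INCHIKEY ", inchikey),
    paste0("AC$MASS_SPECTROMETRY: MS_TYPE ", msType),
    paste0("AC$MASS_SPECTROMETRY: IONIZATION ", ionization),
    if (!is.null(ionMode)) paste0("AC$MASS_SPECTROMETRY: ION_MODE ", ionMode),
    if (!is.null(collisionEnergy))
      paste0("AC$MASS_SPECTROMETRY: COLLISION_ENERGY ", collisionEnergy),
    paste0("PK$NUM_PEAK: ", length(peaks)),
    "PK$PEAK: m/z int. rel.int.",
    vapply(peaks, function(p) sprintf("  %s %s 999", p[1], p[2]),
           character(1)),
    "//")
}

# A SpectrumSet built directly in code (no parsing involved).
tinySpectrumSet <- function(n = 4, msType = "ESI-MS/MS",
                            ionMode = "positive") {
  SpectrumSet(
    data.frame(accession = sprintf("T%03d", seq_len(n)),
               compound_key = sprintf("CMP%02d", rep(seq_len(max(1, n %/% 2)),
                                                     length.out = n)),
               ms_type = msType, ion_mode = ionMode,
               collision_energy_eV = 20),
    lapply(seq_len(n), function(i)
      cbind(mz = c(50 + i, 100 + i, 150.05), intensity = c(10, 50, 100))))
}

# Small but separable labeled set for fast classifier tests.
tinySeparableSet <- function(seed = 1, nBitter = 24, nNonbitter = 24) {
  cfg <- syntheticPreset("separable", seed = seed, nBitter = nBitter,
                         nNonbitter = nNonbitter,
                         spectraPerCompound = list(
                           bitter = stats::setNames(c(.5, .5), 1:2),
                           nonbitter = stats::setNames(c(.5, .5), 1:2)))
  generateSynthetic(cfg)
}
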