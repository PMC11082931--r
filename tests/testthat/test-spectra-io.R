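test_that("MassBank records parse field by field, peaks sorted by m/z", {
  s <- parseMassBankRecord(massbankRecord())
  expect_s4_class(s, "SpectrumSet")
  expect_equal(accessions(s), "MSBNK-TEST-0001")
  expect_equal(compoundKeys(s), "VEQOALNAAJBPNY-UHFFFAOYSA-N")
  expect_equal(msTypes(s), "ESI-MS/MS")
  expect_equal(ionModes(s), "positive")
  expect_equal(collisionEnergies(s), 35)
  pk <- peaksList(s)[[1]]
  expect_equal(pk[, "mz"], c(41.0, 146.05))   # sorted ascending
  expect_equal(pk[, "intensity"], c(12, 999))
})

test_that("missing collision energy encodes as 0; ranges take first value", {
  s <- parseMassBankRecord(massbankRecord(collisionEnergy = NULL))
  expect_equal(collisionEnergies(s), 0)
  s2 <- parseMassBankRecord(massbankRecord(collisionEnergy = "5 to 70 eV"))
  expect_equal(collisionEnergies(s2), 5)
})

test_that("negative-mode and EI records parse with correct enumerations", {
  s <- parseMassBankRecord(massbankRecord(ionMode = "NEGATIVE"))
  expect_equal(ionModes(s), "negative")   # parsed, filtered later
  ei <- parseMassBankRecord(massbankRecord(msType = "MS", ionization = "EI",
                                           ionMode = NULL,
                                           collisionEnergy = "70 eV"))
  expect_equal(msTypes(ei), "EI-MS")
  expect_equal(ionModes(ei), "unknown")
})

test_that("parse errors name the accession and the offending line", {
  bad <- massbankRecord()
  bad <- bad[!grepl("^PK\\$PEAK", bad)]
  expect_error(parseMassBankRecord(bad), "MSBNK-TEST-0001.*PK\\$PEAK")
  mangled <- massbankRecord()
  i <- grep("146.05", mangled)
  mangled[i] <- "  146.05 not-a-number-x x"
  expect_error(parseMassBankRecord(mangled), "malformed peak line")
})

test_that("MSP files parse per entry and enforce the declared peak count", {
  msp <- c("Name: one", "Spectrum_type: ESI-MS/MS", "Ion_mode: positive",
           "Collision_energy: 20", "Num Peaks: 2", "50.1 10", "60.2 99", "",
           "Name: two", "Spectrum_type: EI-MS", "Ion_mode: unknown",
           "Num Peaks: 1", "77.0 100", "")
  s <- readMsp(text = msp)
  expect_equal(length(s), 2L)
  expect_equal(vapply(peaksList(s), nrow, integer(1)), c(2L, 1L))
  short <- sub("Num Peaks: 2", "Num Peaks: 3", msp)
  expect_error(readMsp(text = short), "declared 3 peaks but parsed 2")
})

test_that("write+parse round-trips every field for MSP and the exchange table", {
  set <- tinySpectrumSet(n = 5)
  f <- withr::local_tempfile(fileext = ".msp")
  writeMsp(set, f)
  back <- readMsp(f)
  expect_equal(as.data.frame(spectrumMeta(back)),
               as.data.frame(spectrumMeta(set)))
  expect_equal(peaksList(back), peaksList(set))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeSpectraTable(set, tsv)
  back2 <- readSpectraTable(tsv)
  expect_equal(as.data.frame(spectrumMeta(back2)),
               as.data.frame(spectrumMeta(set)))
  expect_equal(peaksList(back2), peaksList(set))
})

test_that("multi-record MassBank documents split on // terminators", {
  doc <- c(massbankRecord("MSBNK-TEST-0001"),
           massbankRecord("MSBNK-TEST-0002", ionMode = "NEGATIVE"))
  s <- readMassBank(text = doc)
  expect_equal(length(s), 2L)
  expect_equal(accessions(s), c("MSBNK-TEST-0001", "MSBNK-TEST-0002"))
})

test_that("filtering keeps EI-MS regardless of mode and positive tandem only", {
  meta <- data.frame(
    accession = c("a", "b", "c"),
    compound_key = "K",
    ms_type = c("EI-MS", "ESI-MS/MS", "ESI-MS/MS"),
    ion_mode = c("unknown", "positive", "negative"))
  s <- SpectrumSet(meta, rep(list(cbind(100, 1)), 3))
  kept <- filterSpectra(s)
  expect_equal(accessions(kept), c("a", "b"))
  # idempotence
  expect_equal(accessions(filterSpectra(kept)), accessions(kept))
  # empty input is legal
  expect_equal(length(filterSpectra(s[integer(0)])), 0L)
})

test_that("filtering 100 generated records drops exactly the negative ones", {
  n <- 100; nNeg <- 40
  meta <- data.frame(
    accession = sprintf("s%03d", 1:n), compound_key = "K",
    ms_type = "ESI-MS/MS",
    ion_mode = rep(c("negative", "positive"), c(nNeg, n - nNeg)))
  s <- SpectrumSet(meta, rep(list(cbind(100, 1)), n))
  expect_equal(length(filterSpectra(s)), n - nNeg)
})

test_that("intensity normalization maps min to 0 and max to 100", {
  mk <- function(int) SpectrumSet(
    data.frame(accession = "a", compound_key = "K", ms_type = "EI-MS",
               ion_mode = "unknown"),
    list(cbind(seq_along(int) + 50, int)))
  norm <- function(int)
    unname(peaksList(normalizeIntensities(mk(int)))[[1]][, 2])
  expect_equal(norm(c(10, 20, 30)), c(0, 50, 100))
  expect_equal(norm(c(7, 7, 7)), c(100, 100, 100))   # degenerate range
  expect_equal(norm(c(0, 40, 100)), c(0, 40, 100))   # already normalized
  expect_equal(norm(42), 100)                        # single peak
  expect_error(normalizeIntensities(
    SpectrumSet(data.frame(accession = "a", compound_key = "K",
                           ms_type = "EI-MS", ion_mode = "unknown"),
                list(matrix(numeric(0), ncol = 2)))), "no peaks")
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(42)
  for (i in 1:10) {
    int <- rlnorm(sample(2:12, 1), 3, 1)
    mk <- function(v) SpectrumSet(
      data.frame(accession = "a", compound_key = "K", ms_type = "EI-MS",
                 ion_mode = "unknown"),
      list(cbind(seq_along(v) + 50, v)))
    once <- peaksList(normalizeIntensities(mk(int)))[[1]][, 2]
    twice <- peaksList(normalizeIntensities(normalizeIntensities(mk(int))))[[1]][, 2]
    scaled <- peaksList(normalizeIntensities(mk(int * 7.3)))[[1]][, 2]
    expect_equal(twice, once)
    expect_equal(scaled, once)
  }
})
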