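## Reading, filtering and normalizing experimental mass spectra.
##
## Two text formats are supported: MassBank records (ACCESSION /
## AC$MASS_SPECTROMETRY / PK$PEAK blocks) and NIST MSP libraries. Both are
## parsed into SpectrumSet objects; a flat tab-separated exchange table
## (one row per peak) is the internal interchange format.

asLines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

# First numeric token of a free-text field ("35 eV", "5 to 70 eV", "NCE 20%").
firstNumeric <- function(x) {
  m <- regmatches(x, regexpr("[0-9]+\\.?[0-9]*", x))
  if (length(m) == 0 || !nzchar(m)) return(0)
  as.numeric(m)
}

# Map MassBank MS_TYPE + IONIZATION onto the internal ms_type enumeration.
# Single-stage spectra count as EI-MS only under electron ionization;
# MS2 and higher count as ESI-MS/MS unless the ionization says otherwise.
mapMsType <- function(msTypeRaw, ionizationRaw) {
  if (msTypeRaw %in% MS_TYPES) return(msTypeRaw)
  ei <- grepl("\\bEI\\b", ionizationRaw, ignore.case = TRUE)
  esi <- grepl("ESI", ionizationRaw, ignore.case = TRUE)
  tandem <- grepl("^MS[2-9n]", msTypeRaw, ignore.case = TRUE) ||
    grepl("MS/MS|MS-MS", msTypeRaw, ignore.case = TRUE)
  if (ei && !tandem) return("EI-MS")
  if (tandem && (esi || !nzchar(ionizationRaw))) return("ESI-MS/MS")
  "other"
}

mapIonMode <- function(x) {
  x <- toupper(trimws(x))
  if (x %in% c("POSITIVE", "P", "+")) return("positive")
  if (x %in% c("NEGATIVE", "N", "-")) return("negative")
  "unknown"
}

#' Parse one MassBank record
#'
#' Extracts the accession, structure identifiers (SMILES, InChIKey), the
#' instrument metadata (MS type, ionization, ion mode, collision energy)
#' and the `PK$PEAK` peak list from a single MassBank record document.
#' A record without a parseable collision energy is encoded with
#' `collision_energy_eV = 0`; energies given as ranges or with unit text
#' are coerced to their first numeric value.
#'
#' @param text character scalar (whole record) or vector of lines.
#' @return A [SpectrumSet-class] with one spectrum.
#' @examples
#' rec <- c("ACCESSION: MSBNK-TEST-0001",
#'          "AC$MASS_SPECTROMETRY: MS_TYPE MS2",
#'          "AC$MASS_SPECTROMETRY: ION_MODE POSITIVE",
#'          "PK$PEAK: m/z int. rel.int.",
#'          "  146.05 999 999", "//")
#' parseMassBankRecord(rec)
#' @export
parseMassBankRecord <- function(text) {
  lines <- asLines(text)
  field <- function(pat) {
    hit <- grep(pat, lines, value = TRUE)
    if (length(hit) == 0) return("")
    trimws(sub(pat, "", hit[1]))
  }
  accession <- field("^ACCESSION:\\s*")
  if (!nzchar(accession)) stop("MassBank record without an ACCESSION line")
  smiles <- field("^CH\\$SMILES:\\s*")
  if (smiles %in% c("", "N/A", "NA")) smiles <- NA_character_
  inchikey <- field("^CH\\$LINK:\\s*INCHIKEY\\s+")
  compoundKey <- if (nzchar(inchikey)) inchikey else accession

  msTypeRaw <- field("^AC\\$MASS_SPECTROMETRY:\\s*MS_TYPE\\s+")
  ionization <- field("^AC\\$MASS_SPECTROMETRY:\\s*IONIZATION\\s+")
  ionModeRaw <- field("^AC\\$MASS_SPECTROMETRY:\\s*ION_MODE\\s+")
  ceRaw <- field("^AC\\$MASS_SPECTROMETRY:\\s*COLLISION_ENERGY\\s+")

  pkAt <- grep("^PK\\$PEAK:", lines)
  if (length(pkAt) == 0)
    stop("record ", accession, ": missing PK$PEAK block")
  peaks <- list()
  i <- pkAt[1] + 1L
  while (i <= length(lines) && !grepl("^(//|\\S+\\$)", lines[i])) {
    ln <- trimws(lines[i])
    if (nzchar(ln)) {
      tok <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) < 2 || anyNA(vals[1:2]))
        stop("record ", accession, ": malformed peak line ", i, ": '", ln, "'")
      peaks[[length(peaks) + 1L]] <- vals[1:2]
    }
    i <- i + 1L
  }
  if (length(peaks) == 0)
    stop("record ", accession, ": PK$PEAK block contains no peaks")
  pk <- do.call(rbind, peaks)
  colnames(pk) <- c("mz", "intensity")

  SpectrumSet(
    data.frame(accession = accession, compound_key = compoundKey,
               smiles = smiles, ms_type = mapMsType(msTypeRaw, ionization),
               ion_mode = mapIonMode(ionModeRaw),
               collision_energy_eV = firstNumeric(ceRaw),
               stringsAsFactors = FALSE),
    list(pk))
}

#' Read a MassBank record file
#'
#' Accepts a file containing one or more MassBank records separated by
#' `//` terminator lines.
#'
#' @param path path to a MassBank record file.
#' @param text alternatively, the document text itself.
#' @return A [SpectrumSet-class].
#' @export
readMassBank <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else asLines(text)
  idx <- cumsum(c(0L, head(grepl("^//", lines), -1)))
  chunks <- split(lines, idx)
  chunks <- Filter(function(ch) any(grepl("^ACCESSION:", ch)), chunks)
  if (length(chunks) == 0) stop("no MassBank records found")
  do.call(c, unname(lapply(chunks, parseMassBankRecord)))
}

#' Parse a NIST MSP spectral library
#'
#' Entries are `Key: value` headers followed by `Num Peaks: n` and n peak
#' lines; a mismatch between the declared and the parsed peak count is an
#' error. Recognized headers: `Name`, `DB#` (accession), `InChIKey`,
#' `SMILES`, `Spectrum_type`, `Ion_mode`, `Collision_energy`.
#'
#' @param path path to an MSP file.
#' @param text alternatively, the document text itself.
#' @return A [SpectrumSet-class], one spectrum per entry.
#' @seealso [writeMsp()] for the inverse operation.
#' @export
readMsp <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else asLines(text)
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  if (length(starts) == 0) stop("no MSP entries found (no 'Name:' line)")
  ends <- c(starts[-1] - 1L, length(lines))
  sets <- lapply(seq_along(starts), function(k) {
    entry <- lines[starts[k]:ends[k]]
    parseMspEntry(entry, k)
  })
  do.call(c, sets)
}

parseMspEntry <- function(entry, k) {
  hdr <- function(key) {
    pat <- paste0("^", key, ":\\s*")
    hit <- grep(pat, entry, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return("")
    trimws(sub(pat, "", hit[1], ignore.case = TRUE))
  }
  name <- hdr("Name")
  accession <- hdr("DB#")
  if (!nzchar(accession)) accession <- if (nzchar(name)) name else paste0("MSP-", k)
  key <- hdr("InChIKey")
  if (!nzchar(key)) key <- accession
  smiles <- hdr("SMILES")
  if (smiles %in% c("", "N/A", "NA")) smiles <- NA_character_

  npAt <- grep("^Num ?Peaks:", entry, ignore.case = TRUE)
  if (length(npAt) == 0)
    stop("MSP entry '", name, "': missing 'Num Peaks:' line")
  declared <- as.integer(sub("^Num ?Peaks:\\s*", "", entry[npAt[1]],
                             ignore.case = TRUE))
  body <- entry[-seq_len(npAt[1])]
  body <- body[nzchar(trimws(body))]
  # peak pairs may be packed several per line, ';'-separated
  tok <- unlist(strsplit(trimws(unlist(strsplit(body, ";"))), "[\\s,]+",
                         perl = TRUE))
  tok <- tok[nzchar(tok)]
  vals <- suppressWarnings(as.numeric(tok))
  if (anyNA(vals) || length(vals) %% 2 != 0)
    stop("MSP entry '", name, "': malformed peak list")
  pk <- matrix(vals, ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(pk) != declared)
    stop("MSP entry '", name, "': declared ", declared, " peaks but parsed ",
         nrow(pk))

  st <- hdr("Spectrum_type")
  SpectrumSet(
    data.frame(accession = accession, compound_key = key, smiles = smiles,
               ms_type = mapMsType(st, hdr("Ionization")),
               ion_mode = mapIonMode(hdr("Ion_mode")),
               collision_energy_eV = firstNumeric(hdr("Collision_energy")),
               stringsAsFactors = FALSE),
    list(pk))
}

#' Write a SpectrumSet as a NIST MSP library
#'
#' The writer emits the internal enumerations (`EI-MS`, `ESI-MS/MS`,
#' `other`; `positive`/`negative`/`unknown`) verbatim so that
#' `readMsp(writeMsp(x))` round-trips every field.
#'
#' @param x A [SpectrumSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMsp <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- spectrumMeta(x)
  for (i in seq_len(length(x))) {
    writeLines(c(
      paste0("Name: ", m$accession[i]),
      paste0("DB#: ", m$accession[i]),
      paste0("InChIKey: ", m$compound_key[i]),
      if (!is.na(m$smiles[i])) paste0("SMILES: ", m$smiles[i]),
      paste0("Spectrum_type: ", m$ms_type[i]),
      paste0("Ion_mode: ", m$ion_mode[i]),
      paste0("Collision_energy: ", format(m$collision_energy_eV[i], digits = 12)),
      paste0("Num Peaks: ", nrow(x@peaks[[i]]))), con)
    pk <- x@peaks[[i]]
    writeLines(paste(format(pk[, 1], digits = 12, trim = TRUE, scientific = FALSE),
                     format(pk[, 2], digits = 12, trim = TRUE, scientific = FALSE)),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Filter spectra by MS type and ion mode
#'
#' Keeps spectra whose MS type is in `msTypes` and whose ion mode matches
#' `ionMode`. EI-MS records are exempt from the ion-mode predicate: EI
#' sources rarely report a mode, and single-stage electron-ionization
#' spectra are retained regardless.
#'
#' @param x A [SpectrumSet-class].
#' @param msTypes allowed MS types (default the two modeled types).
#' @param ionMode required ion mode for tandem spectra (default
#'   `"positive"`).
#' @return The filtered [SpectrumSet-class] (possibly empty).
#' @export
filterSpectra <- function(x, msTypes = c("EI-MS", "ESI-MS/MS"),
                          ionMode = "positive") {
  keep <- msTypes(x) %in% msTypes &
    (msTypes(x) == "EI-MS" | ionModes(x) == ionMode)
  x[which(keep)]
}

#' Min-max normalize peak intensities to the 0-100 scale
#'
#' Per spectrum, intensities are affinely rescaled so the weakest peak
#' maps to 0 and the strongest to 100. A degenerate spectrum whose peaks
#' all share one intensity (including a single-peak spectrum) maps to
#' all-100, preserving the fact that a peak is present.
#'
#' @param x A [SpectrumSet-class]; every spectrum must have >= 1 peak.
#' @return The normalized [SpectrumSet-class]; m/z values are unchanged.
#' @export
normalizeIntensities <- function(x) {
  x@peaks <- lapply(x@peaks, function(p) {
    if (nrow(p) == 0) stop("cannot normalize a spectrum with no peaks")
    lo <- min(p[, 2]); hi <- max(p[, 2])
    p[, 2] <- if (hi == lo) 100 else (p[, 2] - lo) / (hi - lo) * 100
    p
  })
  validObject(x)
  x
}

#' Read/write the tabular spectrum exchange format
#'
#' A flat tab-separated file with one row per peak and columns
#' `accession`, `compound_key`, `smiles`, `ms_type`, `ion_mode`,
#' `collision_energy_eV`, `mz`, `intensity`. This is the interchange
#' format consumed by the training and prediction stages.
#'
#' @param x A [SpectrumSet-class].
#' @param path file path.
#' @return `writeSpectraTable` returns `path` invisibly;
#'   `readSpectraTable` returns a [SpectrumSet-class].
#' @export
writeSpectraTable <- function(x, path) {
  m <- as.data.frame(spectrumMeta(x))
  n <- vapply(x@peaks, nrow, integer(1))
  tab <- cbind(m[rep(seq_len(nrow(m)), n), , drop = FALSE],
               do.call(rbind, x@peaks))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraTable
#' @export
readSpectraTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  acc <- unique(tab$accession)
  meta <- tab[match(acc, tab$accession),
              c("accession", "compound_key", "smiles", "ms_type", "ion_mode",
                "collision_energy_eV"), drop = FALSE]
  peaks <- lapply(acc, function(a) {
    rows <- tab[tab$accession == a, c("mz", "intensity"), drop = FALSE]
    as.matrix(rows)
  })
  SpectrumSet(meta, peaks)
}
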