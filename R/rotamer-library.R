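# Backbone-dependent rotamer library: chi-angle sets with probabilities,
# indexed by amino acid and a phi/psi bin. Backbone-independent libraries
# use a single `*` wildcard bin.

# Rotatable side-chain dihedral count per supported amino acid.
CHI_COUNTS <- c(GLY = 0L, ALA = 0L, SER = 1L, CYS = 1L, THR = 1L, VAL = 1L,
                LEU = 2L, ILE = 2L, ASP = 2L, ASN = 2L, PHE = 2L, TYR = 2L,
                HIS = 2L, MET = 3L, GLU = 3L, GLN = 3L, LYS = 4L, ARG = 4L)

#' Read a rotamer library
#'
#' Tab-separated file with a `# bin_width: <deg>` header line and columns
#' `aa phi_bin psi_bin prob chi1 chi2 chi3 chi4`. Unused chi columns hold
#' `NA`; `*` in the bin columns declares a backbone-independent
#' (wildcard-bin) entry. Bin labels are bin centers in degrees.
#'
#' @param tsv_path Path to the library file.
#' @return Object of class `rotamer_library`.
#' @export
read_rotamer_library <- function(tsv_path) {
  lines <- readLines(tsv_path)
  hdr <- grep("^#\\s*bin_width", lines, value = TRUE)
  bin_width <- if (length(hdr) > 0)
    as.numeric(sub(".*bin_width[:= ]+", "", hdr[1])) else 10
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("invalid bin_width header in ", tsv_path)
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("aa", "phi_bin", "psi_bin", "prob")
  if (length(setdiff(need, names(tab))) > 0)
    stop("rotamer library must have columns aa/phi_bin/psi_bin/prob")
  chi_cols <- intersect(paste0("chi", 1:4), names(tab))
  entries <- list()
  for (i in seq_len(nrow(tab))) {
    aa <- toupper(tab$aa[i])
    if (!aa %in% names(CHI_COUNTS)) stop("unsupported amino acid: ", aa)
    chis <- as.numeric(tab[i, chi_cols])
    chis <- chis[!is.na(chis)]
    if (length(chis) != CHI_COUNTS[[aa]])
      stop(sprintf("%s expects %d chi angles, row %d supplies %d",
                   aa, CHI_COUNTS[[aa]], i, length(chis)))
    key <- paste(aa, tab$phi_bin[i], tab$psi_bin[i], sep = "|")
    entries[[key]] <- c(entries[[key]],
                        list(list(chis = chis, prob = tab$prob[i])))
  }
  for (key in names(entries)) {
    tot <- sum(vapply(entries[[key]], `[[`, numeric(1), "prob"))
    if (tot > 1 + 1e-6)
      stop("rotamer probabilities for ", key, " sum to ", signif(tot, 4),
           " > 1")
  }
  structure(list(bin_width = bin_width, entries = entries),
            class = "rotamer_library")
}

# Nearest bin center (multiple of bin_width) with boundary ties rounded
# toward -180, wrapped into [-180, 180).
phi_psi_bin <- function(angle, bin_width) {
  b <- bin_width * ceiling(angle / bin_width - 0.5)
  if (b >= 180) b <- b - 360
  if (b < -180) b <- b + 360
  b
}

#' Look up rotamer chi sets for an amino acid at a backbone conformation
#'
#' @param library A `rotamer_library`.
#' @param aa 3-letter code.
#' @param phi,psi Backbone dihedrals in degrees (ignored for wildcard-bin
#'   libraries).
#' @return List of `list(chis, prob)` entries (possibly empty).
#' @export
library_lookup <- function(library, aa, phi, psi) {
  aa <- toupper(aa)
  wild <- library$entries[[paste(aa, "*", "*", sep = "|")]]
  if (!is.null(wild)) return(wild)
  key <- paste(aa, phi_psi_bin(phi, library$bin_width),
               phi_psi_bin(psi, library$bin_width), sep = "|")
  ent <- library$entries[[key]]
  if (is.null(ent)) list() else ent
}
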