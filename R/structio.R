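#' Construct a chain model
#'
#' A `chain_model` is the minimal per-conformer representation used
#' throughout the package: the ordered C-alpha trace of one polymer chain,
#' indexed by author residue numbering. All downstream analyses (interlobe
#' distances, superposition, PCA, hinge angles, Debye profiles) operate on
#' this coarse-grained view; side chains, ligands, waters and ions are
#' deliberately out of scope.
#'
#' @param chain_id single chain identifier.
#' @param resno integer vector of author residue numbers, strictly
#'   increasing.
#' @param resid character vector of 3-letter residue codes, same length.
#' @param xyz numeric matrix (n x 3) of C-alpha coordinates in Angstrom.
#' @param source_id label for the originating file or accession.
#' @return an object of class `chain_model` with fields `chain_id`,
#'   `resno`, `resid`, `xyz`, `source_id`.
#' @examples
#' ch <- chain_model("A", c(1L, 2L), c("ALA", "GLY"),
#'                   rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' extract_sequence(ch)
#' @export
chain_model <- function(chain_id, resno, resid, xyz, source_id = "") {
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(length(resno) == length(resid), nrow(xyz) == length(resno),
            ncol(xyz) == 3)
  if (length(resno) == 0L) stop("chain_model: empty chain")
  if (any(diff(resno) <= 0L))
    stop("chain_model: residue numbers must be strictly increasing")
  if (!all(is.finite(xyz)))
    stop("chain_model: non-finite coordinates")
  dimnames(xyz) <- NULL
  structure(list(chain_id = as.character(chain_id), resno = resno,
                 resid = toupper(as.character(resid)), xyz = xyz,
                 source_id = as.character(source_id)),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> chain %s, %d residues (%d-%d)%s\n",
              x$chain_id, length(x$resno), min(x$resno), max(x$resno),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Number of residues in a chain model
#' @param x a `chain_model`.
#' @export
n_residues <- function(x) length(x$resno)

#' Subdomain scheme for a two-lobed kinase
#'
#' Named author-numbering ranges for the subdomains of the eukaryotic
#' protein kinase fold as found in actinobacterial glucosamine kinases: an
#' N-terminal cap and an intermediate subdomain (together the N-lobe), a
#' short linker that acts as the hinge, and the C-terminal lobe. Defaults
#' follow the SjGlcNK architecture: linker 187-193 and C-lobe 194-438; the
#' cap/intermediate boundary is not structurally enumerated in the source
#' model and defaults to a conventional split of the N-lobe, overridable.
#'
#' @param n_cap integer range (two values, inclusive) for the N-terminal cap.
#' @param intermediate integer range for the intermediate subdomain.
#' @param linker integer range for the interlobe linker.
#' @param c_lobe integer range for the C-terminal lobe.
#' @return object of class `subdomain_scheme`.
#' @examples
#' subdomain_scheme()
#' @export
subdomain_scheme <- function(n_cap = c(1L, 95L),
                             intermediate = c(96L, 186L),
                             linker = c(187L, 193L),
                             c_lobe = c(194L, 438L)) {
  rng <- function(r, nm) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2])
      stop("subdomain_scheme: invalid range for ", nm)
    r
  }
  sch <- list(n_cap = rng(n_cap, "n_cap"),
              intermediate = rng(intermediate, "intermediate"),
              linker = rng(linker, "linker"),
              c_lobe = rng(c_lobe, "c_lobe"))
  sets <- lapply(sch, function(r) seq.int(r[1], r[2]))
  for (i in seq_along(sets)[-1]) for (j in seq_len(i - 1L)) {
    if (length(intersect(sets[[i]], sets[[j]])))
      stop("subdomain_scheme: ranges '", names(sch)[j], "' and '",
           names(sch)[i], "' overlap")
  }
  structure(sch, class = "subdomain_scheme")
}

#' @export
print.subdomain_scheme <- function(x, ...) {
  cat("<subdomain_scheme>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %d-%d\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

# Residue numbers of the mobile N-lobe under a scheme: everything N-terminal
# of the linker (cap + intermediate), the default mobile range for hinge
# analysis.
#' N-lobe residue range implied by a subdomain scheme
#' @param scheme a `subdomain_scheme`.
#' @return integer vector of residue numbers (cap plus intermediate).
#' @export
n_lobe_resnos <- function(scheme) {
  c(seq.int(scheme$n_cap[1], scheme$n_cap[2]),
    seq.int(scheme$intermediate[1], scheme$intermediate[2]))
}

#' Read polymer chains from a PDB or mmCIF file
#'
#' Parses a structure file and returns one `chain_model` per polymer chain
#' containing at least one C-alpha atom. Only protein C-alpha atoms are
#' retained; waters, ligands and ions are dropped. Alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by altloc
#' identifier order). Chains without any C-alpha are skipped with a warning.
#'
#' @param path path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return list of `chain_model` objects, in file chain order.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("read_structure: cannot parse '", path,
                             "' as ", format, ": ", conditionMessage(e)))
  a <- pdb$atom
  ca <- a[a$elety == "CA" & a$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("read_structure: no polymer C-alpha atoms in ", path)
  # resolve altlocs: keep highest occupancy, ties by altloc order
  if (!is.null(ca$alt)) {
    alt <- ifelse(is.na(ca$alt) | ca$alt %in% c("", " "), "", ca$alt)
    occ <- ifelse(is.na(ca$o), 1, ca$o)
    key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(ca)), key), function(idx) {
      idx[order(-occ[idx], alt[idx])][1]
    }), use.names = FALSE)
    ca <- ca[sort(keep), , drop = FALSE]
  }
  src <- basename(path)
  chains <- unique(ca$chain)
  out <- list()
  for (ch in chains) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    cc <- cc[!duplicated(cc$resno), , drop = FALSE]
    cc <- cc[order(cc$resno), , drop = FALSE]
    if (nrow(cc) == 0L) {
      warning("read_structure: chain ", ch, " has no C-alpha atoms; skipped")
      next
    }
    out[[length(out) + 1L]] <- chain_model(
      chain_id = ch, resno = cc$resno, resid = cc$resid,
      xyz = cbind(cc$x, cc$y, cc$z), source_id = src)
  }
  if (length(out) == 0L) stop("read_structure: no usable chains in ", path)
  out
}

# 3-letter -> 1-letter amino acid map; selenomethionine maps to M,
# anything unrecognised to X.
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "U", PYL = "O")

#' One-letter sequence of a chain model
#'
#' @param chain a `chain_model`.
#' @return single string; unknown residue codes become `X` (a message is
#'   emitted once per call when this happens).
#' @export
extract_sequence <- function(chain) {
  one <- unname(.aa3to1[chain$resid])
  bad <- is.na(one)
  if (any(bad)) {
    message("extract_sequence: ", sum(bad),
            " non-standard residue(s) mapped to X")
    one[bad] <- "X"
  }
  paste(one, collapse = "")
}

#' Write a chain model as minimal PDB text
#'
#' Emits C-alpha ATOM records (fixed-width PDB columns, coordinates to
#' 3 decimals) plus TER/END. Round-tripping through [read_structure()]
#' reproduces residue numbers exactly and coordinates to 3 decimals.
#'
#' @param chain a `chain_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(chain$resno)) {
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, substr(chain$resid[i], 1, 3), substr(chain$chain_id, 1, 1),
      chain$resno[i], chain$xyz[i, 1], chain$xyz[i, 2], chain$xyz[i, 3]),
      con)
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Write several chain models into one PDB file
#' @param chains list of `chain_model`s; chain identifiers should differ.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chains_pdb <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (chain in chains) {
    for (i in seq_along(chain$resno)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, substr(chain$resid[i], 1, 3), substr(chain$chain_id, 1, 1),
        chain$resno[i], chain$xyz[i, 1], chain$xyz[i, 2], chain$xyz[i, 3]),
        con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of upper-case sequences, in file order;
#'   duplicate identifiers are suffixed `.2`, `.3`, ... with a warning.
#' @export
read_fasta_seqs <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  seqs <- apply(fa$ali, 1, paste, collapse = "")
  seqs <- toupper(gsub("-", "", seqs, fixed = TRUE))
  ids <- fa$id
  if (anyDuplicated(ids)) {
    warning("read_fasta_seqs: duplicate sequence ids suffixed")
    ids <- make.unique(ids, sep = ".")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

# UTF-8 tab-separated table with header; the one table writer used by the
# command-line layer.
#' Write a data frame as a TSV file
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
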