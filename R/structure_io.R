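# Reading PDB structures, assigning the bundled charge/radius parameters,
# centering on the center of mass, and Chothia segment annotation.

guessElement <- function(name, elesy = NULL) {
  if (!is.null(elesy) && nzchar(elesy)) return(toupper(elesy))
  s <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name))
  first <- toupper(substr(s, 1, 1))
  if (first %in% names(elementMasses)) first else "C"
}

defaultChainRoles <- function(ids) {
  roles <- rep("other", length(ids))
  roles[toupper(ids) %in% c("H", "B")] <- "heavy"
  roles[toupper(ids) %in% c("L", "A")] <- "light"
  stats::setNames(roles, ids)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}; waters and hetero groups are
#' dropped by default, hydrogens are retained if present.
#'
#' @param path PDB file path
#' @param chains optional named character vector mapping chain id to role
#'   (\code{"heavy"}, \code{"light"}, \code{"other"}); by default chains named
#'   H/B are heavy and L/A light
#' @param keepHetero keep non-water HETATM records
#' @return an \linkS4class{FvStructure} (charges/radii unassigned)
#' @export
readPDB <- function(path, chains = NULL, keepHetero = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  keep <- !(a$resid %in% c("HOH", "WAT", "DOD", "TIP", "SOL"))
  if (!keepHetero) keep <- keep & a$type == "ATOM"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after filtering")
  elem <- mapply(guessElement, a$elety, ifelse(is.na(a$elesy), "", a$elesy))
  chain <- ifelse(is.na(a$chain), " ", a$chain)
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = unname(elem),
                      resname = a$resid, resno = a$resno,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      chain = chain, x = a$x, y = a$y, z = a$z,
                      charge = NA_real_, radius = NA_real_,
                      mass = unname(elementMasses[elem]),
                      stringsAsFactors = FALSE)
  atoms$mass[is.na(atoms$mass)] <- 12.011
  ids <- unique(atoms$chain)
  roles <- defaultChainRoles(ids)
  if (!is.null(chains)) roles[names(chains)] <- chains
  new("FvStructure", atoms = atoms, chains = roles,
      provenance = list(source = path, transforms = list()))
}

#' Write a structure to a PDB file
#'
#' @param s an \linkS4class{FvStructure}
#' @param path output file
#' @export
writePDB <- function(s, path) {
  a <- s@atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno, resid = a$resname,
                   eleno = a$serial, elety = a$name, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elesy = a$element)
  invisible(path)
}

residueKey <- function(a) paste(a$chain, a$resno, a$insert, sep = "|")

#' Assign partial charges and van der Waals radii
#'
#' Uses the bundled minimal parameter table: formal charges localized on
#' Asp/Glu carboxylates, the Lys amine and the Arg guanidine group, small
#' self-cancelling partial charges on backbone N/CA/C/O, zero elsewhere, and
#' per-element van der Waals radii (united-atom radii when the structure has
#' no hydrogens).  Histidine and the chain termini are neutral by default.
#'
#' @param s an \linkS4class{FvStructure}
#' @param hisCharged protonate histidine (+1 split over ND1/NE2)
#' @param chargedTermini put +1 on each chain's first backbone N and -1 on the
#'   last residue's terminal carboxyl oxygen
#' @param fallback if FALSE, an unknown residue name is an error; if TRUE it
#'   receives backbone charges and zero sidechain charge
#' @return the structure with \code{charge}, \code{radius} and \code{mass} set
#' @export
assignParameters <- function(s, hisCharged = FALSE, chargedTermini = FALSE,
                             fallback = TRUE) {
  a <- s@atoms
  if (!fallback) {
    bad <- setdiff(unique(a$resname), standardResidues)
    if (length(bad))
      stop("unknown residue(s) with fallback disabled: ", paste(bad, collapse = ", "))
  }
  bb <- readTable("backbone_charges")
  grp <- readTable("charge_groups")
  if (hisCharged) grp <- rbind(grp, readTable("his_charged"))
  rad <- readTable("element_radii")

  charge <- rep(0, nrow(a))
  m <- match(a$name, bb$atom)
  charge[!is.na(m)] <- bb$charge[m[!is.na(m)]]
  key <- paste(a$resname, a$name)
  g <- match(key, paste(grp$resname, grp$atom))
  charge[!is.na(g)] <- grp$charge[g[!is.na(g)]]
  charge[a$element == "H"] <- 0

  if (chargedTermini) {
    for (ch in unique(a$chain)) {
      idx <- which(a$chain == ch)
      res <- a$resno[idx]
      firstN <- idx[a$name[idx] == "N" & res == min(res)]
      if (length(firstN)) charge[firstN[1]] <- charge[firstN[1]] + 1
      lastRes <- idx[res == max(res)]
      oxt <- lastRes[a$name[lastRes] == "OXT"]
      tgt <- if (length(oxt)) oxt[1] else lastRes[a$name[lastRes] == "O"][1]
      if (!is.na(tgt)) charge[tgt] <- charge[tgt] - 1
    }
  }

  hasH <- any(a$element == "H")
  rcol <- if (hasH) "radius" else "radius_united"
  r <- rad[[rcol]][match(a$element, rad$element)]
  r[is.na(r)] <- if (hasH) 1.7 else 1.9

  a$charge <- charge
  a$radius <- r
  a$mass <- unname(elementMasses[a$element])
  a$mass[is.na(a$mass)] <- 12.011
  initialize(s, atoms = a)
}

#' Expected formal charge of a residue under the bundled convention
#' @keywords internal
residueFormalCharge <- function(resname, hisCharged = FALSE) {
  z <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)[resname]
  z[is.na(z)] <- 0
  if (hisCharged) z[resname == "HIS"] <- 1
  unname(z)
}

#' Move the center of mass to the Cartesian origin
#'
#' @param s an \linkS4class{FvStructure} with masses assigned
#' @return the translated structure; the translation is logged in provenance
#' @export
canonicalize <- function(s) {
  a <- s@atoms
  w <- a$mass / sum(a$mass)
  com <- c(sum(a$x * w), sum(a$y * w), sum(a$z * w))
  a$x <- a$x - com[1]; a$y <- a$y - com[2]; a$z <- a$z - com[3]
  prov <- s@provenance
  prov$transforms <- c(prov$transforms, list(list(type = "translate", shift = -com)))
  initialize(s, atoms = a, provenance = prov)
}

#' Label residues as framework or CDR by Chothia numbering
#'
#' Residues of heavy/light chains whose Chothia number falls inside the
#' bundled CDR ranges (L1 24-34, L2 50-56, L3 89-97, H1 26-32, H2 52-56,
#' H3 95-102) are labelled with that CDR; other numbered residues are
#' framework.  Chains with role \code{other}, or all residues when no
#' numbering is supplied, are labelled \code{unknown}.
#'
#' @param s an \linkS4class{FvStructure}
#' @param numbering \code{"none"} or a data.frame with columns chain, resno,
#'   insert, chothia giving the Chothia number of every heavy/light residue
#' @param cdrRanges optional replacement for the bundled range table
#' @return a \linkS4class{SegmentMap}
#' @export
annotateSegments <- function(s, numbering = "none", cdrRanges = NULL) {
  a <- s@atoms
  res <- unique(a[, c("chain", "resno", "insert")])
  res$segment <- "unknown"
  if (!identical(numbering, "none")) {
    if (is.null(cdrRanges)) cdrRanges <- readTable("chothia_cdr")
    roles <- s@chains
    if (!"insert" %in% names(numbering)) numbering$insert <- ""
    key <- paste(numbering$chain, numbering$resno, numbering$insert, sep = "|")
    for (i in seq_len(nrow(res))) {
      role <- roles[[res$chain[i]]]
      if (!role %in% c("heavy", "light")) next
      j <- match(paste(res$chain[i], res$resno[i], res$insert[i], sep = "|"), key)
      if (is.na(j)) next
      num <- numbering$chothia[j]
      rr <- cdrRanges[cdrRanges$chain == role & num >= cdrRanges$start &
                        num <= cdrRanges$end, ]
      res$segment[i] <- if (nrow(rr)) rr$cdr[1] else "framework"
    }
    covered <- res$segment != "unknown" |
      !vapply(res$chain, function(ch) s@chains[[ch]] %in% c("heavy", "light"), TRUE)
    if (!all(covered)) {
      miss <- res[!covered, ]
      stop("numbering does not cover residue(s): ",
           paste(paste0(miss$chain, miss$resno, miss$insert), collapse = ", "))
    }
  }
  new("SegmentMap", table = res)
}
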