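# Idealised selectivity-filter scaffolds.
#
# A fourfold tetramer of pseudo-backbone atoms (N, H, C, O plus the S_side
# side-chain oxygens) for residues V59-S70, built so that the two conformers
# reproduce the geometric signatures of the crystal and T62-carbonyl-flipped
# filter states: in the crystal form every vicinal amide H-H distance in
# 61LTTVG65 is < 4 A and the T63NH-T60CO / V64NH-V59CO hydrogen bonds are
# satisfied; in the flipped form the T62H-T63H distance is exactly 4.5 A, the
# two crystal bonds are broken and V64NH-T62CO is formed instead.  These are
# synthetic constraint-driven scaffolds, not crystallographic coordinates.

.sf_resnames <- c("59" = "VAL", "60" = "THR", "61" = "LEU", "62" = "THR",
                  "63" = "THR", "64" = "VAL", "65" = "GLY", "66" = "ASP",
                  "67" = "GLY", "68" = "ASN", "69" = "PHE", "70" = "SER")

# z of residue i in the single-chain template (T62 at z = 0; the strand is
# compressed above G65 where the chain folds back into the vestibule rim).
.sf_res_z <- function(i) ifelse(i <= 65, 2.8 * (i - 62), 11.2 + 1.5 * (i - 66))

# Single-chain template in local (u = radial, v = tangential, z) coordinates.
.sf_template <- function(conformer, widen) {
  rows <- list()
  add <- function(resno, atom, u, v, z)
    rows[[length(rows) + 1]] <<- data.frame(resno = resno, atom = atom,
                                            u = u, v = v, z = z)
  flipped <- conformer == "flipped_T62"
  for (i in 59:70) {
    z <- .sf_res_z(i)
    if (i == 63 && flipped) {
      # peptide-plane rotation displaces the T63 amide; H62-H63 becomes 4.5 A
      zf <- sqrt(4.5^2 - 0.4^2 - 1.5^2)          # = 4.2237, exact by construction
      add(i, "N", 4.6, 1.5, zf); add(i, "H", 5.6, 1.5, zf)
    } else {
      add(i, "N", 5.0, 0, z); add(i, "H", 6.0, 0, z)
    }
    w <- if (i %in% c(63, 64)) widen / 2 else 0
    if (i == 59) {                     # acceptor of V64NH in the crystal form
      if (flipped) { add(i, "C", 8.0, 0, 4.37); add(i, "O", 9.23, 0, 4.37) }
      else         { add(i, "C", 8.0, 0, 4.37); add(i, "O", 8.0, 0, 5.60) }
    } else if (i == 60) {              # acceptor of T63NH in the crystal form
      add(i, "C", 8.0, 0, 1.57); add(i, "O", 8.0, 0, 2.80)
    } else if (i == 62 && flipped) {   # flipped carbonyl accepts V64NH
      add(i, "C", 6.77, 0, 5.6); add(i, "O", 8.0, 0, 5.6)
    } else if (i == 66) {              # D66 carbonyl reoriented toward the portal
      add(i, "C", 6.8, 1.5, 10.6); add(i, "O", 8.0, 1.8, 10.6)
      add(i, "OD1", 6.2, -5.2, 10.0)
    } else if (i == 69) {
      add(i, "C", 6.8, -1.5, 8.6); add(i, "O", 8.0, -1.8, 8.6)
    } else {                           # pore-lining carbonyl, O toward the axis
      add(i, "C", 4.63 + w, 0, z + 1.4); add(i, "O", 3.40 + w, 0, z + 1.4)
      if (i == 70) add(i, "OG", 10.6, 0, 9.6)
    }
  }
  do.call(rbind, rows)
}

#' Generate an idealised fourfold selectivity-filter scaffold
#'
#' @param conformer `"crystal"` or `"flipped_T62"`.
#' @param widen uniform increase (A) of the opposing T63/V64 carbonyl-oxygen
#'   separations relative to the crystal scaffold.
#' @param origin 3-vector placing the pore axis (default at the coordinate
#'   origin, axis along +z).
#' @return data.frame of class `sf_structure` with columns `chain`, `resno`,
#'   `resname`, `atom`, `x`, `y`, `z`.
#' @export
gen_sf_scaffold <- function(conformer = c("crystal", "flipped_T62"), widen = 0,
                            origin = c(0, 0, 0)) {
  if (is.character(conformer) && length(conformer) == 1 &&
      !conformer %in% c("crystal", "flipped_T62"))
    stop("unknown conformer label: ", conformer)
  conformer <- match.arg(conformer)
  tmpl <- .sf_template(conformer, widen)
  chains <- lapply(SUBUNITS, function(ch) {
    phi <- .subunit_azimuth[[ch]]
    er <- c(cos(phi), sin(phi)); et <- c(-sin(phi), cos(phi))
    data.frame(chain = ch, resno = tmpl$resno,
               resname = unname(.sf_resnames[as.character(tmpl$resno)]),
               atom = tmpl$atom,
               x = origin[1] + tmpl$u * er[1] + tmpl$v * et[1],
               y = origin[2] + tmpl$u * er[2] + tmpl$v * et[2],
               z = origin[3] + tmpl$z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, chains)
  rownames(out) <- NULL
  structure(out, class = c("sf_structure", "data.frame"),
            conformer = conformer, widen = widen)
}

#' Write / read an sf_structure as PDB
#'
#' Thin wrappers around bio3d.  Amide hydrogens are written as atom name `H`;
#' structures read from PDB that lack them can be passed through
#' [reconstruct_amide_h()] before contact analysis.
#'
#' @param structure an `sf_structure` data.frame.
#' @param path file path.
#' @return `path` (write) or an `sf_structure` (read).
#' @export
write_structure_pdb <- function(structure, path) {
  n <- nrow(structure)
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = structure$resno, resid = structure$resname,
                   chain = structure$chain, elety = structure$atom,
                   eleno = seq_len(n))
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  structure(data.frame(chain = a$chain, resno = a$resno, resname = a$resid,
                       atom = a$elety, x = a$x, y = a$y, z = a$z,
                       stringsAsFactors = FALSE),
            class = c("sf_structure", "data.frame"))
}

#' Reconstruct amide hydrogens from backbone geometry
#'
#' For residues lacking an `H` atom, places it 1.0 A from N along the
#' direction bisecting the N->C(prev) and N->CA directions, reversed (the
#' standard sp2 amide construction).  Falls back to the outward radial
#' direction from the pore axis when CA or the previous C is missing.
#'
#' @param x an `sf_structure`.
#' @param axis_origin 2-vector (x, y) of the pore axis for the fallback.
#' @return the structure with `H` rows added where they were missing.
#' @export
reconstruct_amide_h <- function(x, axis_origin = c(0, 0)) {
  out <- x
  for (ch in unique(out$chain)) {
    sub <- out[out$chain == ch, ]
    for (rn in sort(unique(sub$resno))) {
      res <- sub[sub$resno == rn, ]
      if (any(res$atom == "H") || !any(res$atom == "N")) next
      N <- as.numeric(res[res$atom == "N", c("x", "y", "z")][1, ])
      CA <- if (any(res$atom == "CA"))
        as.numeric(res[res$atom == "CA", c("x", "y", "z")][1, ]) else NULL
      Cp <- sub[sub$resno == rn - 1 & sub$atom == "C", c("x", "y", "z")]
      Cp <- if (nrow(Cp)) as.numeric(Cp[1, ]) else NULL
      dir <- if (!is.null(CA) && !is.null(Cp)) {
        u1 <- (CA - N) / sqrt(sum((CA - N)^2))
        u2 <- (Cp - N) / sqrt(sum((Cp - N)^2))
        d <- -(u1 + u2); d / sqrt(sum(d^2))
      } else {
        d <- c(N[1:2] - axis_origin, 0)
        if (sum(d^2) == 0) c(1, 0, 0) else d / sqrt(sum(d^2))
      }
      H <- N + dir
      out <- rbind(out, data.frame(chain = ch, resno = rn,
                                   resname = res$resname[1], atom = "H",
                                   x = H[1], y = H[2], z = H[3],
                                   stringsAsFactors = FALSE))
    }
  }
  structure(out[order(out$chain, out$resno), ],
            class = c("sf_structure", "data.frame"))
}
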