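# Shared in-code fixtures: tiny structures, file fixtures, small utilities.

# 3-residue single-chain structure; residue 3 lacks its Calpha
tinyStructure <- function() {
    StructureModel("tiny",
        chain = c("A", "A", "A"), resno = 1:3,
        resname = c("ALA", "GLY", "SER"),
        x = c(1, 4, NA), y = c(2, 6, NA), z = c(3, 3, NA),
        present = c(TRUE, TRUE, FALSE))
}

miniPdbLines <- function() c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   6.000   3.000  1.00  0.00           C",
    "ATOM      4  N   SER A   3       9.000   9.000   9.000  1.00  0.00           N",
    "HETATM    5  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END")

miniCifLines <- function() c(
    "data_mini", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C CA . GLY A 1 2 ? 4.000 6.000 3.000 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 4 N N . SER A 1 3 ? 9.000 9.000 9.000 1.00 0.00 ? 3 SER A N 1",
    "#")

# proper rotation about the z axis, plus a generic composed rotation
rotZ <- function(th) matrix(c(cos(th), -sin(th), 0,
                              sin(th),  cos(th), 0,
                              0, 0, 1), 3L, 3L, byrow = TRUE)
rotX <- function(th) matrix(c(1, 0, 0,
                              0, cos(th), -sin(th),
                              0, sin(th),  cos(th)), 3L, 3L, byrow = TRUE)

# random cross-link table (not canonical on input, possibly duplicated)
randomRawLinks <- function(n, nProteins = 5L, maxRes = 50L) {
    data.frame(
        pa = sprintf("P%02d", sample.int(nProteins, n, TRUE)),
        ra = sample.int(maxRes, n, TRUE),
        pb = sprintf("P%02d", sample.int(nProteins, n, TRUE)),
        rb = sample.int(maxRes, n, TRUE),
        stringsAsFactors = FALSE)
}

# exhaustive 256-level Otsu oracle following the same histogram convention
otsuOracle <- function(img) {
    v <- as.numeric(img)
    lo <- min(v); hi <- max(v)
    bin <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
    best <- -Inf; bestK <- NA
    for (k in 0:254) {
        g0 <- v[bin <= k]; g1 <- v[bin > k]
        if (!length(g0) || !length(g1)) next
        w0 <- length(g0) / length(v); w1 <- 1 - w0
        # between-class variance on bin indices, as the implementation uses
        m0 <- mean(bin[bin <= k]); m1 <- mean(bin[bin > k])
        s <- w0 * w1 * (m0 - m1)^2
        if (s > best) { best <- s; bestK <- k }
    }
    lo + (bestK + 1) * (hi - lo) / 256
}
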