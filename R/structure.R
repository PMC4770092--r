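#' Attachment-point distance change between two structures
#'
#' Computes the C-alpha to C-alpha distance between the two handle
#' attachment residues in an open and a closed structure and returns the
#' distance change on closing. For adenylate kinase the attachment
#' positions are residues 42 and 144 and the relevant entries are the
#' open (2RH5) and inhibitor-bound closed (2RGX) crystal structures,
#' which must be downloaded by the user; the distance change is about
#' 1.7 nm. Requires the `bio3d` package.
#'
#' @param pdb_open,pdb_closed Paths (or accession codes resolvable by
#'   `bio3d::read.pdb`) of the open and closed structures.
#' @param residues Length-2 vector of attachment residue numbers.
#' @param chain Optional chain identifier.
#' @return List with `d_open_nm`, `d_closed_nm`, `change_nm`
#'   (open minus closed).
#' @export
attachment_distance_change <- function(pdb_open, pdb_closed,
                                       residues = c(42, 144),
                                       chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("the bio3d package is required for the structural check")
  }
  dist_one <- function(path) {
    pdb <- bio3d::read.pdb(path)
    sel <- bio3d::atom.select(pdb, elety = "CA", resno = residues,
                              chain = chain)
    xyz <- matrix(pdb$xyz[sel$xyz], ncol = 3, byrow = TRUE)
    if (nrow(xyz) != 2) {
      stop("expected 2 CA atoms for residues ",
           paste(residues, collapse = ", "), " in ", path,
           "; found ", nrow(xyz))
    }
    sqrt(sum((xyz[1, ] - xyz[2, ])^2)) / 10  # Angstrom -> nm
  }
  d_open <- dist_one(pdb_open)
  d_closed <- dist_one(pdb_closed)
  list(d_open_nm = d_open, d_closed_nm = d_closed,
       change_nm = d_open - d_closed)
}
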