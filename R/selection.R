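# Atom selection over a topology table.

#' Select atoms from a topology
#'
#' Simple conjunctive filter over topology columns. All supplied criteria must
#' hold; `heavy = TRUE` drops hydrogens.
#'
#' @param top `fd_topology` (or any data.frame with the same columns).
#' @param chain,resid,name,resname,element optional vectors of allowed values.
#' @param heavy if TRUE, exclude element H.
#' @return integer vector of atom row indices (possibly empty).
#' @export
select_atoms <- function(top, chain = NULL, resid = NULL, name = NULL,
                         resname = NULL, element = NULL, heavy = FALSE) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(chain))   keep <- keep & top$chain %in% chain
  if (!is.null(resid))   keep <- keep & top$resid %in% resid
  if (!is.null(name))    keep <- keep & top$name %in% name
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  if (!is.null(element)) keep <- keep & top$element %in% element
  if (heavy)             keep <- keep & top$element != "H"
  which(keep)
}
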