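#' Construct a topology
#'
#' A topology is the immutable per-atom table shared by every frame of a
#' trajectory: atom names, residue numbering, partial charges, Lennard-Jones
#' C6/C12 parameters and hydrogen-bond roles, plus the donor--hydrogen
#' covalent bond table needed to evaluate hydrogen-bond geometry.
#'
#' @param atoms data.frame with columns `name`, `resnum`, `resname` and
#'   optionally `chain` (default `"A"`), `element` (default: first letter of
#'   `name`), `charge` (elementary charges, default 0), `c6`
#'   (kJ mol^-1 nm^6, default 0), `c12` (kJ mol^-1 nm^12, default 0) and
#'   `role` (one of `"donor"`, `"acceptor"`, `"hydrogen"`, `"none"`;
#'   default `"none"`).
#' @param bonds data.frame with integer columns `donor` and `hydrogen`
#'   (1-based atom indices) listing covalent donor--hydrogen bonds, or
#'   `NULL` for none.
#'
#' @return An object of class `"topology"`: a list with elements `atoms`
#'   (completed data.frame) and `bonds`.
#'
#' @details Invariants enforced: C6 and C12 are non-negative; roles are from
#'   the allowed set; every atom flagged `"hydrogen"` appears exactly once
#'   as the hydrogen of a bond whose donor is flagged `"donor"`; bond
#'   indices are valid; no hydrogen is bound to two donors.
#'
#' @export
topology <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  required <- c("name", "resnum", "resname")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  atoms$name    <- as.character(atoms$name)
  atoms$resnum  <- as.integer(atoms$resnum)
  atoms$resname <- as.character(atoms$resname)
  if (is.null(atoms$chain))   atoms$chain   <- "A"
  if (is.null(atoms$element)) atoms$element <- substr(gsub("[^A-Za-z].*$", "", atoms$name), 1L, 1L)
  if (is.null(atoms$charge))  atoms$charge  <- 0
  if (is.null(atoms$c6))      atoms$c6      <- 0
  if (is.null(atoms$c12))     atoms$c12     <- 0
  if (is.null(atoms$role))    atoms$role    <- "none"
  atoms$charge <- as.numeric(atoms$charge)
  atoms$c6  <- as.numeric(atoms$c6)
  atoms$c12 <- as.numeric(atoms$c12)
  atoms$role <- as.character(atoms$role)
  atoms <- atoms[, c("name", "element", "resnum", "resname", "chain",
                     "charge", "c6", "c12", "role")]
  rownames(atoms) <- NULL

  if (any(atoms$c6 < 0) || any(atoms$c12 < 0))
    stop("Lennard-Jones C6 and C12 parameters must be non-negative")
  bad_role <- setdiff(unique(atoms$role), c("donor", "acceptor", "hydrogen", "none"))
  if (length(bad_role))
    stop("unknown hbond role(s): ", paste(bad_role, collapse = ", "))

  if (is.null(bonds)) {
    bonds <- data.frame(donor = integer(0), hydrogen = integer(0))
  } else {
    stopifnot(is.data.frame(bonds), all(c("donor", "hydrogen") %in% names(bonds)))
    bonds <- data.frame(donor = as.integer(bonds$donor),
                        hydrogen = as.integer(bonds$hydrogen))
    if (nrow(bonds)) {
      idx <- c(bonds$donor, bonds$hydrogen)
      if (any(idx < 1L) || any(idx > n))
        stop("bond table refers to atom indices outside 1..", n)
      if (anyDuplicated(bonds$hydrogen))
        stop("a hydrogen is bound to more than one donor in the bond table")
    }
  }

  hyd <- which(atoms$role == "hydrogen")
  unbound <- setdiff(hyd, bonds$hydrogen)
  if (length(unbound))
    stop("hydrogen atom(s) without a bonded donor: index ",
         paste(unbound, collapse = ", "),
         " (", paste(atoms$name[unbound], collapse = ", "), ")")
  if (nrow(bonds)) {
    not_h <- bonds$hydrogen[atoms$role[bonds$hydrogen] != "hydrogen"]
    if (length(not_h))
      stop("bond table hydrogen index ", paste(not_h, collapse = ", "),
           " is not flagged as role 'hydrogen'")
  }

  structure(list(atoms = atoms, bonds = bonds), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resnum)), "residues,",
      nrow(x$bonds), "donor-hydrogen bond(s)\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a [topology()]
#' @return integer atom count
#' @export
n_atoms <- function(top) {
  if (inherits(top, "trajectory")) top <- top$topology
  nrow(top$atoms)
}

#' Read a plain-text topology sidecar
#'
#' The sidecar is a whitespace-delimited table, one row per atom with
#' columns `index name resnum resname charge c6 c12 role` (`index` is
#' 0-based and must be contiguous), optionally followed by a `BONDS` section
#' with one `donor_index hydrogen_index` pair per line (also 0-based).
#' Lines starting with `#` are comments. The format is engine-neutral:
#' charges and C6/C12 values are taken at face value in GROMACS units
#' (e, kJ mol^-1 nm^6, kJ mol^-1 nm^12).
#'
#' @param path file path.
#' @return a [topology()].
#' @export
read_topology_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bsplit <- which(lines == "BONDS")
  if (length(bsplit) > 1L) stop("multiple BONDS sections in sidecar")
  if (length(bsplit) == 1L) {
    atom_lines <- lines[seq_len(bsplit - 1L)]
    bond_lines <- lines[-seq_len(bsplit)]
  } else {
    atom_lines <- lines
    bond_lines <- character(0)
  }
  if (!length(atom_lines)) stop("sidecar contains no atom rows")
  at <- utils::read.table(text = atom_lines, header = FALSE,
                          col.names = c("index", "name", "resnum", "resname",
                                        "charge", "c6", "c12", "role"),
                          colClasses = c("integer", "character", "integer",
                                         "character", "numeric", "numeric",
                                         "numeric", "character"))
  if (!identical(at$index, seq_len(nrow(at)) - 1L))
    stop("sidecar atom indices must be 0-based and contiguous")
  bonds <- NULL
  if (length(bond_lines)) {
    bd <- utils::read.table(text = bond_lines, header = FALSE,
                            col.names = c("donor", "hydrogen"),
                            colClasses = "integer")
    bonds <- data.frame(donor = bd$donor + 1L, hydrogen = bd$hydrogen + 1L)
  }
  topology(at[, -1L], bonds)
}

#' Write a topology sidecar
#'
#' Inverse of [read_topology_sidecar()].
#'
#' @param top a [topology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology_sidecar <- function(top, path) {
  stopifnot(inherits(top, "topology"))
  at <- top$atoms
  rows <- sprintf("%d %s %d %s %.6g %.8g %.8g %s",
                  seq_len(nrow(at)) - 1L, at$name, at$resnum, at$resname,
                  at$charge, at$c6, at$c12, at$role)
  out <- c("# index name resnum resname charge c6 c12 role", rows)
  if (nrow(top$bonds)) {
    out <- c(out, "BONDS",
             sprintf("%d %d", top$bonds$donor - 1L, top$bonds$hydrogen - 1L))
  }
  writeLines(out, path)
  invisible(path)
}

#' Select atoms by a query expression
#'
#' Supports conjunctions of `name` and `resid` clauses, e.g.
#' `"name CA and resid 25-149"`, `"resid 57-63"`,
#' `"name N,CA,C and resid 50-56,64-70"`. Values within a clause may be
#' separated by commas or spaces; residue values may be single numbers or
#' `a-b` ranges. Clauses are combined with `and` (intersection); values
#' within a clause are alternatives (union).
#'
#' @param top a [topology()] (or a trajectory, whose topology is used).
#' @param query selection expression.
#' @return sorted integer vector of 1-based atom indices with class
#'   `"atom_selection"`; attribute `"query"` records the expression.
#'   An empty result is an error, never a silent empty selection.
#' @export
select_atoms <- function(top, query) {
  if (inherits(top, "trajectory")) top <- top$topology
  stopifnot(inherits(top, "topology"), is.character(query), length(query) == 1L)
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  if (!length(clauses)) stop("empty selection query")
  keep <- rep(TRUE, nrow(top$atoms))
  for (cl in clauses) {
    parts <- strsplit(trimws(cl), "[,[:space:]]+")[[1]]
    kw <- parts[1]
    vals <- parts[-1]
    if (!length(vals)) stop("selection clause without values: '", cl, "'")
    if (kw == "name") {
      keep <- keep & top$atoms$name %in% vals
    } else if (kw == "resid") {
      resnums <- integer(0)
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
          ab <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
          resnums <- c(resnums, seq(ab[1], ab[2]))
        } else if (grepl("^-?[0-9]+$", v)) {
          resnums <- c(resnums, as.integer(v))
        } else stop("cannot parse resid value '", v, "'")
      }
      keep <- keep & top$atoms$resnum %in% resnums
    } else {
      stop("unknown selection keyword '", kw, "' (supported: name, resid)")
    }
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection '", query, "' matches no atoms")
  structure(sort(idx), class = "atom_selection", query = query)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("Selection", shQuote(attr(x, "query") %||% ""), ":",
      length(x), "atoms\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate an index vector against a topology/trajectory; returns plain integer
check_selection <- function(sel, n, what = "selection") {
  sel <- as.integer(sel)
  if (!length(sel)) stop(what, " is empty")
  if (anyDuplicated(sel)) stop(what, " contains duplicate atom indices")
  if (any(sel < 1L) || any(sel > n))
    stop(what, " contains atom indices outside 1..", n)
  sort(sel)
}
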