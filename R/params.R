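# ---- nonbonded parameter handling ------------------------------------------

# Small built-in per-element Lennard-Jones table (sigma in Angstrom, epsilon
# in kcal/mol). These are generic desk-scale defaults, not a force field;
# any per-(residue, atom) table supplied by the user overrides them.
ELEMENT_LJ <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR"),
  lj_sigma = c(2.50, 3.40, 3.25, 3.00, 3.60, 3.74, 3.12, 3.47, 3.60),
  lj_epsilon = c(0.030, 0.086, 0.170, 0.210, 0.250, 0.200, 0.061, 0.265, 0.320),
  stringsAsFactors = FALSE
)

element_lj_defaults <- function(elements) {
  m <- match(toupper(elements), ELEMENT_LJ$element)
  data.frame(lj_sigma = ifelse(is.na(m), 0, ELEMENT_LJ$lj_sigma[m]),
             lj_epsilon = ifelse(is.na(m), 0, ELEMENT_LJ$lj_epsilon[m]))
}

#' Built-in per-(residue, atom) parameter table
#'
#' Currently carries TIP3P-style water charges and oxygen Lennard-Jones
#' parameters; intended as the seed a user-supplied table extends.
#'
#' @return data frame with columns `res_name`, `atom_name`, `charge`,
#'   `lj_sigma`, `lj_epsilon`.
#' @export
builtin_param_table <- function() {
  w <- function(atom, q, s, e)
    data.frame(res_name = WATER_RESNAMES, atom_name = atom, charge = q,
               lj_sigma = s, lj_epsilon = e, stringsAsFactors = FALSE)
  rbind(w("O", -0.834, 3.15061, 0.1521),
        w("OW", -0.834, 3.15061, 0.1521),
        w("H1", 0.417, 0, 0), w("H2", 0.417, 0, 0),
        w("HW1", 0.417, 0, 0), w("HW2", 0.417, 0, 0))
}

#' Read a nonbonded parameter table
#'
#' Plain delimited text (tab or comma, autodetected) with a header row and
#' columns `res_name`, `atom_name`, `charge`, `lj_sigma`, `lj_epsilon`
#' (charge in elementary charges, sigma in Angstrom, epsilon in kcal/mol).
#'
#' @param path file path.
#' @return data frame with the five columns.
#' @export
read_parameter_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("res_name", "atom_name", "charge", "lj_sigma", "lj_epsilon")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("parameter table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab[, need]
}

#' Write a nonbonded parameter table
#'
#' @param table data frame as returned by [read_parameter_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign nonbonded parameters to a model
#'
#' Fills the `charge`, `lj_sigma` and `lj_epsilon` atom columns: charges
#' default to zero and Lennard-Jones parameters to the built-in per-element
#' table; entries of the built-in water table and of the optional
#' user-supplied per-(residue, atom) table override these, the user table
#' taking final precedence.
#'
#' @param model a `protofibril`.
#' @param table optional data frame or path of a parameter table.
#' @return the parameterized `protofibril`.
#' @export
assign_parameters <- function(model, table = NULL) {
  if (is.character(table)) table <- read_parameter_table(table)
  a <- model$atoms
  lj <- element_lj_defaults(a$element)
  a$charge <- 0
  a$lj_sigma <- lj$lj_sigma
  a$lj_epsilon <- lj$lj_epsilon
  for (tab in Filter(Negate(is.null), list(builtin_param_table(), table))) {
    m <- match(paste(a$res_name, a$name), paste(tab$res_name, tab$atom_name))
    hit <- !is.na(m)
    a$charge[hit] <- tab$charge[m[hit]]
    a$lj_sigma[hit] <- tab$lj_sigma[m[hit]]
    a$lj_epsilon[hit] <- tab$lj_epsilon[m[hit]]
  }
  model$atoms <- a
  model
}
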