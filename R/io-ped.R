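# Six-column pedigree files.

#' Read a six-column PED pedigree file
#'
#' Parses the standard whitespace-delimited pedigree dialect
#' (family, individual, father, mother, sex, phenotype). Roles are inferred
#' from parent pointers: the individual whose parent fields are non-zero is
#' the proband; the individuals pointed at are the father and mother. Sex
#' codes 1/2 map to XY/XX and phenotype 2 to affected. A phenotype code of 0
#' is taken as unaffected with a logged warning (unknown status). Parents
#' that are absent from the file (pointer `0` or an id with no own row) are
#' materialised as placeholder members with `present = FALSE`, so every
#' family always carries a proband, mother and father slot.
#'
#' @param path Path to a PED file.
#' @return A tibble of family members with columns `family_id`, `sample_id`,
#'   `role` (`proband`/`mother`/`father`), `sex` (`XX`/`XY`), `affected`
#'   and `present`.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) != 6) {
    stop_format(sprintf("PED file must have exactly 6 columns, found %d", ncol(raw)))
  }
  names(raw) <- c("family_id", "sample_id", "father_id", "mother_id",
                  "sex_code", "phenotype_code")
  if (!all(raw$sex_code %in% c("1", "2"))) {
    stop_format("unknown sex code in PED (expected 1 = XY, 2 = XX)")
  }
  if (!all(raw$phenotype_code %in% c("0", "1", "2"))) {
    stop_format("unknown phenotype code in PED (expected 0/1/2)")
  }
  if (any(raw$phenotype_code == "0")) {
    warn("PED phenotype code 0 (unknown status) treated as unaffected",
         class = "triofunnel_unknown_status")
  }
  ped <- as_tibble(raw)
  ped$sex <- if_else(ped$sex_code == "1", "XY", "XX")
  ped$affected <- ped$phenotype_code == "2"

  members <- lapply(split(ped, ped$family_id), function(fam) {
    has_parents <- fam$father_id != "0" | fam$mother_id != "0"
    probands <- fam[has_parents, ]
    if (nrow(probands) != 1) {
      stop_format(sprintf(
        "family %s must contain exactly one individual with parent pointers (found %d); multiplex families are encoded as a proband plus an affected parent",
        fam$family_id[[1]], nrow(probands)))
    }
    proband <- probands[1, ]
    if (!proband$affected) {
      stop_format(sprintf("proband of family %s must be affected", proband$family_id))
    }
    one_parent <- function(id, role, sex) {
      if (id != "0" && id %in% fam$sample_id) {
        row <- fam[fam$sample_id == id, ]
        if (row$sex != sex) {
          stop_format(sprintf("%s of family %s has sex code inconsistent with role",
                              role, fam$family_id[[1]]))
        }
        tibble(family_id = row$family_id, sample_id = row$sample_id,
               role = role, sex = row$sex, affected = row$affected,
               present = TRUE)
      } else {
        tibble(family_id = fam$family_id[[1]], sample_id = NA_character_,
               role = role, sex = sex, affected = FALSE, present = FALSE)
      }
    }
    bind_rows(
      tibble(family_id = proband$family_id, sample_id = proband$sample_id,
             role = "proband", sex = proband$sex, affected = TRUE,
             present = TRUE),
      one_parent(proband$mother_id, "mother", "XX"),
      one_parent(proband$father_id, "father", "XY")
    )
  })
  bind_rows(members)
}
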