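#' File formats of the pipeline
#'
#' All tabular interchange uses plain CSV with a fixed, documented column
#' order and empty fields for missing values; genotypes use whitespace-
#' delimited dosage text with a SNP-id header; curve stores use JSON. Each
#' writer has a matching reader and `read(write(x))` restores `x`.
#'
#' @name woolres-formats
NULL

#' @describeIn woolres-formats pedigree CSV: `animal,sire,dam,generation`
#'   (0 = unknown parent).
#' @param ped pedigree `data.frame`.
#' @param path file path.
#' @export
write_pedigree_csv <- function(ped, path) {
  write.csv(ped[, intersect(c("animal", "sire", "dam", "generation", "sex",
                              "flock_year"), names(ped))],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' @describeIn woolres-formats read a pedigree CSV.
#' @export
read_pedigree_csv <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(animal = "integer", sire = "integer",
                                 dam = "integer"))
  if ("flock_year" %in% names(ped)) ped$flock_year[ped$flock_year == ""] <- NA
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @describeIn woolres-formats long-format phenotype CSV:
#'   `animal,series,position,value,flock_year,sex,brt,weaning_age,
#'   staple_length,sampling_age`.
#' @param series long series `data.frame`.
#' @export
write_series_csv <- function(series, path) {
  cols <- c("animal", "series", "position", "value", "flock_year", "sex",
            "brt", "weaning_age", "staple_length", "sampling_age")
  write.csv(series[, intersect(cols, names(series))], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' @describeIn woolres-formats read a phenotype CSV.
#' @export
read_series_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(brt = "character"))
}

#' @describeIn woolres-formats genotype dosages as whitespace-delimited text:
#'   header of SNP ids, then one row per animal (`animal` id first).
#' @param M dosage matrix from [simulate_genotypes()].
#' @export
write_genotypes_txt <- function(M, path) {
  df <- data.frame(animal = rownames(M), as.data.frame(M), check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(path)
}

#' @describeIn woolres-formats read a genotype dosage file.
#' @export
read_genotypes_txt <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$animal
  storage.mode(M) <- "integer"
  M
}

#' @describeIn woolres-formats tidy trait CSV:
#'   `animal,series,flock_year,trait,lambda,value,outlier_flag`.
#' @param traits trait `data.frame` from the traits stage.
#' @export
write_traits_csv <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @describeIn woolres-formats read a trait CSV.
#' @export
read_traits_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @describeIn woolres-formats curve store (knots, order, coefficients and
#'   domain per animal) as JSON.
#' @param curves named list of `smooth_curve` objects.
#' @export
write_curve_store <- function(curves, path) {
  payload <- lapply(curves, function(cv) {
    list(coefficients = cv$coefficients, knots = cv$knots, order = cv$order,
         domain = cv$domain, lambda = cv$lambda)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @describeIn woolres-formats read a curve store back into `smooth_curve`
#'   objects (without cached grid evaluations).
#' @export
read_curve_store <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(cv) {
    structure(list(coefficients = as.numeric(cv$coefficients),
                   knots = as.numeric(cv$knots), order = as.integer(cv$order),
                   domain = as.numeric(cv$domain), lambda = as.numeric(cv$lambda),
                   grid = NULL, values = NULL),
              class = "smooth_curve")
  })
}

# Write every stage output present in a pipeline result and return a manifest
# with md5 content hashes (reruns with identical config and seed reproduce
# identical hashes for the deterministic stages).
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(res$sim)) {
    write_pedigree_csv(res$sim$pedigree, p("pedigree.csv"))
    write_series_csv(res$sim$series, p("series.csv"))
    write.csv(res$sim$truth, p("truth.csv"), row.names = FALSE, na = "")
    files <- c(files, "pedigree.csv", "series.csv", "truth.csv")
    if (!is.null(res$sim$genotypes)) {
      write_genotypes_txt(res$sim$genotypes, p("genotypes.txt"))
      files <- c(files, "genotypes.txt")
    }
  }
  if (!is.null(res$standardized)) {
    write_series_csv(res$standardized, p("standardized.csv"))
    files <- c(files, "standardized.csv")
  }
  if (!is.null(res$alignment)) {
    al <- lapply(names(res$alignment), function(key) {
      ga <- res$alignment[[key]]
      grid <- attr(ga, "grid")
      do.call(rbind, lapply(attr(ga, "lambda_grid"), function(lam) {
        entry <- ga[[paste0("lambda_", lam)]]
        data.frame(group = key, lambda = lam,
                   position = rep(grid, ncol(entry$aligned)),
                   animal = rep(colnames(entry$aligned), each = length(grid)),
                   aligned = as.vector(entry$aligned),
                   warp = as.vector(vapply(entry$warps, function(w) w$gamma,
                                           numeric(length(grid)))))
      }))
    })
    write.csv(do.call(rbind, al), p("aligned.csv"), row.names = FALSE, na = "")
    files <- c(files, "aligned.csv")
  }
  if (!is.null(res$traits)) {
    write_traits_csv(res$traits$traits, p("traits.csv"))
    write.csv(res$traits$windows, p("windows.csv"), row.names = FALSE, na = "")
    files <- c(files, "traits.csv", "windows.csv")
  }
  if (!is.null(res$varcomp)) {
    tab <- report_tables(res)$h2_table
    write.csv(tab, p("varcomp.csv"), row.names = FALSE, na = "")
    files <- c(files, "varcomp.csv")
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  snapshot <- res$config
  snapshot$out_dir <- NULL
  jsonlite::write_json(
    list(created = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("woolres")),
         config = snapshot,
         files = manifest),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}
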