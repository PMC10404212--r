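#' Read and write descriptor tables
#'
#' Descriptor tables travel as plain CSV (RFC 4180, "." decimal) or ARFF
#' (the WEKA format: numeric attributes plus one nominal class attribute).
#' Both round-trip losslessly through the matching writer; the class
#' attribute is identified by the name `"class"` or, failing that, the last
#' nominal attribute.
#'
#' @param path File path.
#' @param format `"csv"` or `"arff"`; the default guesses from the file
#'   extension.
#' @return `read_table_file()` returns a tibble with a character `class`
#'   column; writers return `path` invisibly.
#' @export
read_table_file <- function(path, format = c("auto", "csv", "arff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "arff") return(read_arff(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cls_col <- if ("class" %in% names(df)) "class" else {
    nom <- names(df)[vapply(df, is.character, logical(1))]
    if (length(nom) == 0L) stop("no class column found", call. = FALSE)
    nom[length(nom)]
  }
  for (nm in setdiff(names(df), cls_col)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop("non-numeric value in column '", nm, "' at data line ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
  }
  df[[cls_col]] <- as.character(df[[cls_col]])
  names(df)[names(df) == cls_col] <- "class"
  tibble::as_tibble(df)
}

#' @rdname read_table_file
#' @param table Data frame with numeric feature columns and a class column.
#' @param class_col Class column name.
#' @export
write_table_csv <- function(table, path, class_col = "class") {
  stopifnot(class_col %in% names(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_table_file
#' @param relation ARFF relation name.
#' @export
write_arff <- function(table, path, relation = "incfrnn",
                       class_col = "class") {
  stopifnot(is.data.frame(table), class_col %in% names(table))
  feats <- setdiff(names(table), class_col)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@relation ", relation), con)
  for (nm in feats) {
    if (!is.numeric(table[[nm]])) stop("feature '", nm, "' is not numeric",
                                       call. = FALSE)
    writeLines(paste0("@attribute ", .arff_quote(nm), " numeric"), con)
  }
  lev <- sort(unique(as.character(table[[class_col]])))
  writeLines(paste0("@attribute class {", paste(lev, collapse = ","), "}"), con)
  writeLines("@data", con)
  body <- apply(cbind(format(as.matrix(table[feats]), digits = 17,
                             trim = TRUE, scientific = FALSE),
                      as.character(table[[class_col]])),
                1L, paste, collapse = ",")
  writeLines(body, con)
  invisible(path)
}

.arff_quote <- function(x) {
  ifelse(grepl("[ ,{}']", x), paste0("'", x, "'"), x)
}

#' @rdname read_table_file
#' @export
read_arff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  attr_names <- character(0)
  attr_types <- character(0)
  nominal_levels <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "%")) next
    low <- tolower(ln)
    if (startsWith(low, "@relation")) next
    if (startsWith(low, "@attribute")) {
      m <- regmatches(ln, regexec(
        "^@[Aa][Tt][Tt][Rr][Ii][Bb][Uu][Tt][Ee]\\s+('[^']+'|\\S+)\\s+(.+)$", ln))[[1]]
      if (length(m) != 3L) stop("malformed @attribute at line ", i, call. = FALSE)
      nm <- gsub("^'|'$", "", m[2])
      tp <- trimws(m[3])
      attr_names <- c(attr_names, nm)
      if (grepl("^\\{", tp)) {
        lev <- trimws(strsplit(gsub("[{}]", "", tp), ",")[[1]])
        attr_types <- c(attr_types, "nominal")
        nominal_levels[[nm]] <- lev
      } else if (tolower(tp) %in% c("numeric", "real", "integer")) {
        attr_types <- c(attr_types, "numeric")
      } else {
        stop("unsupported attribute type '", tp, "' at line ", i, call. = FALSE)
      }
      next
    }
    if (startsWith(low, "@data")) { data_start <- i + 1L; break }
    stop("malformed header at line ", i, ": ", ln, call. = FALSE)
  }
  if (is.na(data_start)) stop("no @data section", call. = FALSE)
  if (length(attr_names) == 0L) stop("no attributes declared", call. = FALSE)
  body <- lines[data_start:length(lines)]
  keep <- !(trimws(body) == "" | startsWith(trimws(body), "%"))
  body <- body[keep]
  cells <- strsplit(body, ",")
  nc <- length(attr_names)
  bad_len <- which(lengths(cells) != nc)
  if (length(bad_len) > 0L) {
    stop("wrong field count at line ", data_start + bad_len[1] - 1L, call. = FALSE)
  }
  mat <- do.call(rbind, cells)
  df <- list()
  for (j in seq_len(nc)) {
    col <- trimws(mat[, j])
    if (attr_types[j] == "numeric") {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num)) {
        stop("non-numeric value in attribute '", attr_names[j],
             "' at line ", data_start + which(is.na(num))[1] - 1L, call. = FALSE)
      }
      df[[attr_names[j]]] <- num
    } else {
      df[[attr_names[j]]] <- gsub("^'|'$", "", col)
    }
  }
  df <- tibble::as_tibble(df)
  nom <- attr_names[attr_types == "nominal"]
  cls <- if ("class" %in% names(df)) "class" else {
    if (length(nom) == 0L) stop("no class attribute", call. = FALSE)
    nom[length(nom)]
  }
  names(df)[names(df) == cls] <- "class"
  df
}

#' Write a run manifest
#'
#' Records the resolved configuration, package version and timestamp of one
#' experiment run as JSON, for reproducibility audits.
#'
#' @param config A named list (e.g. from [read_experiment_config()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(list(
    config = config,
    package_version = as.character(utils::packageVersion("incfrnn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
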