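# Derive a reproducible child seed from a base seed plus arbitrary tags.
# Polynomial rolling hash mod (2^31 - 1), so the result is a valid R seed.
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(part), "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

# Clip values into [0, 1] while preserving dim/attributes.
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stop_arg <- function(...) stop(..., call. = FALSE)

is_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

check_image <- function(x, what = "image") {
  if (!is_image(x)) stop_arg(what, " must be an H x W x 3 numeric array")
  invisible(x)
}

# Coerce a single image / list of images / 4-d array to a list of images.
as_image_list <- function(images) {
  if (is_image(images)) return(list(images))
  if (is.array(images) && length(dim(images)) == 4L) {
    return(lapply(seq_len(dim(images)[4]), function(i) images[, , , i]))
  }
  if (is.list(images)) {
    lapply(images, check_image)
    return(images)
  }
  stop_arg("expected an image, a list of images, or an H x W x 3 x B array")
}

# Nearest-neighbour resize; adequate for the low-resolution synthetic frames.
resize_image <- function(image, size) {
  check_image(image)
  h <- size[1]
  w <- if (length(size) > 1) size[2] else size[1]
  d <- dim(image)
  if (d[1] == h && d[2] == w) return(image)
  ri <- pmin(d[1], pmax(1L, round((seq_len(h) - 0.5) * d[1] / h + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(w) - 0.5) * d[2] / w + 0.5)))
  image[ri, ci, , drop = FALSE]
}
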