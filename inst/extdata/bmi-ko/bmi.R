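
bmi <- function(inputs) {
    height <- inputs$features$height
    weight <- inputs$features$weight
    if (is.null(height) || is.null(weight))
        stop("missing 'height' or 'weight' feature")
    if (height == 0) stop("division by zero: height is 0")
    if (height < 0) stop("domain error: height must be > 0")
    weight / height / height * 703
}
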