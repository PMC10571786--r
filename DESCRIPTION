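Package: nbisim
Title: Simulated Narrow Band Imaging for White-Light Endoscopy Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts white-light endoscopy frames (including video capsule
    endoscopy frames, which lack narrow band imaging hardware) into simulated
    narrow-band-imaging (NBI) frames by Reinhard-style statistics transfer in
    Ruderman's decorrelated l-alpha-beta color space: RGB is mapped to LMS cone
    responses, log-transformed, decorrelated, and each axis is affinely remapped
    so its mean and standard deviation match those of an NBI reference. Includes
    the three-metric evaluation protocol used for such conversions (structural
    similarity, gray-level Shannon entropy difference, and peak signal-to-noise
    ratio), a deterministic synthetic endoscopy-frame generator for testing
    without clinical data, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite
Suggests:
    tiff,
    jpeg,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
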