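test_that("WAV round-trips preserve samples and rate", {
  t <- seq(0, 1 - 1 / 2000, by = 1 / 2000)
  rec <- Recording(0.8 * sin(2 * pi * 50 * t), rate = 2000)

  f32 <- tempfile(fileext = ".wav")
  writeWav(rec, f32, encoding = "float32")
  back <- readWav(f32)
  expect_equal(samplingRate(back), 2000)
  expect_equal(samples(back), samples(rec), tolerance = 1e-7)

  p16 <- tempfile(fileext = ".wav")
  writeWav(rec, p16, encoding = "pcm16")
  back16 <- readWav(p16)
  expect_equal(samplingRate(back16), 2000)
  # within 1 LSB of the 16-bit encoding
  expect_lt(max(abs(samples(back16) - samples(rec))), 1 / 32768)
  unlink(c(f32, p16))
})

test_that("full-scale PCM-16 rescales to ~1 and units are never guessed", {
  # hand-written minimal WAV, independent of writeWav
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  pcm <- writeBin(rep(32767L, 100), raw(), 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(pcm)), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")   # PCM
  writeBin(1L, con, 2L, endian = "little")   # mono
  writeBin(2000L, con, 4L, endian = "little")
  writeBin(4000L, con, 4L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(pcm)), con, 4L, endian = "little")
  writeBin(pcm, con)
  close(con)

  rec <- readWav(path)
  expect_equal(samples(rec), rep(1, 100), tolerance = 1e-3)
  expect_identical(signalUnits(rec), "raw")
  unlink(path)
})

test_that("multi-channel WAV is rejected naming the channel count", {
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  pcm <- writeBin(rep(0L, 40), raw(), 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(pcm)), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")   # stereo
  writeBin(2000L, con, 4L, endian = "little")
  writeBin(8000L, con, 4L, endian = "little")
  writeBin(4L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(pcm)), con, 4L, endian = "little")
  writeBin(pcm, con)
  close(con)
  expect_error(readWav(path), "2 channels")
  unlink(path)
})

test_that("WAV encoding agrees with an independent reader/writer", {
  # scipy.io.wavfile as the cross-implementation oracle
  t <- seq(0, 0.1 - 1 / 2000, by = 1 / 2000)
  rec <- Recording(sin(2 * pi * 80 * t), rate = 2000)
  ours <- tempfile(fileext = ".wav")
  theirs <- tempfile(fileext = ".wav")
  csv <- tempfile(fileext = ".csv")
  writeWav(rec, ours, encoding = "float32")
  script <- sprintf(paste0(
    "import numpy as np\nfrom scipy.io import wavfile\n",
    "r, x = wavfile.read('%s')\n",
    "assert r == 2000 and x.dtype == np.float32, (r, x.dtype)\n",
    "np.savetxt('%s', x)\n",
    "wavfile.write('%s', 2000, x)\n"), ours, csv, theirs)
  status <- system2("python", "-", input = script, stdout = TRUE,
                    stderr = TRUE)
  expect_false(any(grepl("Error|Traceback", status)))
  expect_equal(scan(csv, quiet = TRUE), samples(rec), tolerance = 1e-7)
  back <- readWav(theirs)
  expect_equal(samples(back), samples(rec), tolerance = 1e-7)
  expect_equal(samplingRate(back), 2000)
  unlink(c(ours, theirs, csv))
})

test_that("CSV signal reading infers the rate and rejects bad spacing", {
  path <- tempfile(fileext = ".csv")
  n <- 100
  df <- data.frame(time_s = (0:(n - 1)) * 5e-4, amplitude = rnorm(n))
  write.csv(df, path, row.names = FALSE)
  rec <- readCsvSignal(path)
  expect_equal(samplingRate(rec), 2000)
  expect_equal(samples(rec), df$amplitude)

  df_bad <- df; df_bad$time_s[51:100] <- df_bad$time_s[51:100] + 0.01
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(readCsvSignal(path), "non-uniform")

  df_na <- df; df_na$amplitude[c(3, 7)] <- NA
  write.csv(df_na, path, row.names = FALSE)
  expect_error(readCsvSignal(path), "3, 7")

  write.csv(data.frame(a = 1:5, b = 1:5), path, row.names = FALSE)
  expect_error(readCsvSignal(path), "missing column")
  unlink(path)
})

test_that("CSV signal round-trip is the identity", {
  rec <- generateStationary(seed = 4L, durationS = 0.5)
  path <- tempfile(fileext = ".csv")
  writeCsvSignal(rec, path)
  back <- readCsvSignal(path)
  expect_equal(samples(back), samples(rec))
  expect_equal(samplingRate(back), samplingRate(rec), tolerance = 1e-9)
  unlink(path)
})

test_that("event markers round-trip through the sidecar and stay in range", {
  t <- seq(0, 1 - 5e-4, by = 5e-4)
  ev <- data.frame(time_s = c(0.25, 0.9), label = c("beep", "fatigue_button"))
  rec <- Recording(sin(2 * pi * 30 * t), events = ev)
  path <- tempfile(fileext = ".wav")
  writeWav(rec, path)
  back <- readWav(path)
  expect_equal(recordingEvents(back), ev)
  # event outside the recording violates the class invariant
  expect_error(Recording(rnorm(10), rate = 10,
                         events = data.frame(time_s = 5, label = "x")),
               "within")
  unlink(c(path, paste0(path, ".events.csv")))
})

test_that("feature tables round-trip and refuse empties", {
  rec <- generateStationary(seed = 2L, durationS = 3)
  fs <- isometricFeatures(preprocessRecording(rec), mvc = 1)
  path <- tempfile(fileext = ".csv")
  writeFeatures(fs, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 3)          # header + one row per window
  back <- readFeatures(path)
  expect_equal(featureTable(back), featureTable(fs), tolerance = 1e-12)
  empty <- new("FeatureSeries", windowStart = numeric(0), rms = numeric(0),
               mdf = numeric(0), mnf = numeric(0), defined = logical(0),
               kind = "isometric")
  expect_error(writeFeatures(empty, path), "empty")
  unlink(path)
})
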