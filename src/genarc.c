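/* Codec backends (zlib / bzip2 / xz), CRC32 and the fixture PRNG.
 *
 * All compressors are pure byte-to-byte functions: identical (data, level)
 * always yields identical output, which the container layer relies on for
 * reproducibility.  Decompressors recover the original length by growing
 * the output buffer, so no self-describing header is stored with blocks.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#include <string.h>
#include <stdint.h>

#include <zlib.h>
#include <bzlib.h>
#include <lzma.h>

static SEXP raw_copy(const unsigned char *buf, R_xlen_t n)
{
    SEXP out = PROTECT(allocVector(RAWSXP, n));
    if (n > 0)
        memcpy(RAW(out), buf, (size_t) n);
    UNPROTECT(1);
    return out;
}

/* ---- CRC32 (zlib polynomial) ---- */

SEXP C_crc32(SEXP data)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    if (XLENGTH(data) > 0)
        crc = crc32(crc, RAW(data), (uInt) XLENGTH(data));
    return ScalarReal((double) crc);
}

/* ---- gzip (zlib stream format) ---- */

SEXP C_gzip_compress(SEXP data, SEXP level)
{
    uLong src_len = (uLong) XLENGTH(data);
    uLongf dest_len = compressBound(src_len);
    unsigned char *buf = (unsigned char *) R_alloc(dest_len ? dest_len : 1, 1);
    int rc = compress2(buf, &dest_len, RAW(data), src_len, asInteger(level));
    if (rc != Z_OK)
        error("gzip compression failed (zlib error %d)", rc);
    return raw_copy(buf, (R_xlen_t) dest_len);
}

SEXP C_gzip_decompress(SEXP data, SEXP size_hint)
{
    uLong src_len = (uLong) XLENGTH(data);
    uLongf cap = (uLongf) asReal(size_hint);
    if (cap < 64) cap = 64;
    for (;;) {
        unsigned char *buf = (unsigned char *) R_alloc(cap, 1);
        uLongf dest_len = cap;
        int rc = uncompress(buf, &dest_len, RAW(data), src_len);
        if (rc == Z_OK)
            return raw_copy(buf, (R_xlen_t) dest_len);
        if (rc == Z_BUF_ERROR) {
            if (cap > (uLongf) 1 << 30)
                error("gzip decompression exceeded 1 GiB output limit");
            cap *= 2;
            continue;
        }
        error("corrupt gzip data (zlib error %d)", rc);
    }
}

/* ---- bzip2 ---- */

SEXP C_bzip2_compress(SEXP data, SEXP level)
{
    unsigned int src_len = (unsigned int) XLENGTH(data);
    unsigned int dest_len = src_len + src_len / 100 + 600;
    unsigned char *buf = (unsigned char *) R_alloc(dest_len, 1);
    int rc = BZ2_bzBuffToBuffCompress((char *) buf, &dest_len,
                                      (char *) RAW(data), src_len,
                                      asInteger(level), 0, 0);
    if (rc != BZ_OK)
        error("bzip2 compression failed (error %d)", rc);
    return raw_copy(buf, (R_xlen_t) dest_len);
}

SEXP C_bzip2_decompress(SEXP data, SEXP size_hint)
{
    unsigned int src_len = (unsigned int) XLENGTH(data);
    unsigned int cap = (unsigned int) asReal(size_hint);
    if (cap < 64) cap = 64;
    for (;;) {
        unsigned char *buf = (unsigned char *) R_alloc(cap, 1);
        unsigned int dest_len = cap;
        int rc = BZ2_bzBuffToBuffDecompress((char *) buf, &dest_len,
                                            (char *) RAW(data), src_len, 0, 0);
        if (rc == BZ_OK)
            return raw_copy(buf, (R_xlen_t) dest_len);
        if (rc == BZ_OUTBUFF_FULL) {
            if (cap > 1u << 30)
                error("bzip2 decompression exceeded 1 GiB output limit");
            cap *= 2;
            continue;
        }
        error("corrupt bzip2 data (error %d)", rc);
    }
}

/* ---- lzma (xz stream format) ---- */

SEXP C_lzma_compress(SEXP data, SEXP preset)
{
    size_t src_len = (size_t) XLENGTH(data);
    size_t cap = lzma_stream_buffer_bound(src_len);
    unsigned char *buf = (unsigned char *) R_alloc(cap, 1);
    size_t out_pos = 0;
    lzma_ret rc = lzma_easy_buffer_encode((uint32_t) asInteger(preset),
                                          LZMA_CHECK_CRC32, NULL,
                                          RAW(data), src_len,
                                          buf, &out_pos, cap);
    if (rc != LZMA_OK)
        error("lzma compression failed (error %d)", (int) rc);
    return raw_copy(buf, (R_xlen_t) out_pos);
}

SEXP C_lzma_decompress(SEXP data, SEXP size_hint)
{
    size_t src_len = (size_t) XLENGTH(data);
    size_t cap = (size_t) asReal(size_hint);
    if (cap < 64) cap = 64;
    for (;;) {
        unsigned char *buf = (unsigned char *) R_alloc(cap, 1);
        uint64_t memlimit = UINT64_MAX;
        size_t in_pos = 0, out_pos = 0;
        lzma_ret rc = lzma_stream_buffer_decode(&memlimit, 0, NULL,
                                                RAW(data), &in_pos, src_len,
                                                buf, &out_pos, cap);
        if (rc == LZMA_OK)
            return raw_copy(buf, (R_xlen_t) out_pos);
        if (rc == LZMA_BUF_ERROR) {
            if (cap > (size_t) 1 << 30)
                error("lzma decompression exceeded 1 GiB output limit");
            cap *= 2;
            continue;
        }
        error("corrupt lzma data (error %d)", (int) rc);
    }
}

/* ---- splitmix64 uniform deviates for the fixture generators ----
 *
 * Fixed here (not delegated to R's RNG) so that generated fixtures are
 * bit-identical across R versions and platforms.  Seed is passed as a
 * double and must be a non-negative integer below 2^53.
 */

static uint64_t splitmix64_next(uint64_t *state)
{
    uint64_t z = (*state += UINT64_C(0x9E3779B97F4A7C15));
    z = (z ^ (z >> 30)) * UINT64_C(0xBF58476D1CE4E5B9);
    z = (z ^ (z >> 27)) * UINT64_C(0x94D049BB133111EB);
    return z ^ (z >> 31);
}

SEXP C_rng_uniform(SEXP seed, SEXP n)
{
    uint64_t state = (uint64_t) asReal(seed);
    R_xlen_t m = (R_xlen_t) asReal(n);
    SEXP out = PROTECT(allocVector(REALSXP, m));
    double *p = REAL(out);
    for (R_xlen_t i = 0; i < m; i++) {
        /* top 53 bits -> double in [0, 1) */
        p[i] = (double) (splitmix64_next(&state) >> 11) *
               (1.0 / 9007199254740992.0);
    }
    UNPROTECT(1);
    return out;
}

/* ---- registration ---- */

static const R_CallMethodDef call_methods[] = {
    {"C_crc32",            (DL_FUNC) &C_crc32,            1},
    {"C_gzip_compress",    (DL_FUNC) &C_gzip_compress,    2},
    {"C_gzip_decompress",  (DL_FUNC) &C_gzip_decompress,  2},
    {"C_bzip2_compress",   (DL_FUNC) &C_bzip2_compress,   2},
    {"C_bzip2_decompress", (DL_FUNC) &C_bzip2_decompress, 2},
    {"C_lzma_compress",    (DL_FUNC) &C_lzma_compress,    2},
    {"C_lzma_decompress",  (DL_FUNC) &C_lzma_decompress,  2},
    {"C_rng_uniform",      (DL_FUNC) &C_rng_uniform,      2},
    {NULL, NULL, 0}
};

void R_init_genarc(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
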