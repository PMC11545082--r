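#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* CRC-32 (IEEE 802.3, reflected polynomial 0xedb88320) over a raw vector.
   Needed for PNG chunk checksums; returned as double because the value
   does not fit in a signed 32-bit R integer. */
SEXP C_crc32(SEXP bytes)
{
    static unsigned int tab[256];
    static int init = 0;
    if (!init) {
        for (unsigned int n = 0; n < 256; n++) {
            unsigned int c = n;
            for (int k = 0; k < 8; k++)
                c = (c & 1) ? 0xedb88320U ^ (c >> 1) : c >> 1;
            tab[n] = c;
        }
        init = 1;
    }
    R_xlen_t len = XLENGTH(bytes);
    const unsigned char *p = RAW(bytes);
    unsigned int c = 0xffffffffU;
    for (R_xlen_t i = 0; i < len; i++)
        c = tab[(c ^ p[i]) & 0xff] ^ (c >> 8);
    return ScalarReal((double)(c ^ 0xffffffffU));
}

static const R_CallMethodDef callMethods[] = {
    {"C_crc32", (DL_FUNC) &C_crc32, 1},
    {NULL, NULL, 0}
};

void R_init_cagepose(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
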