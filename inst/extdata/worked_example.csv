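id,glasses,va_unc_l,va_unc_r,va_cor_l,va_cor_r,va_ph_l,va_ph_r,age,sex,residence
u001,no,6/18,6/24,,,6/9,6/12,34,female,urban
u002,no,6/24,6/36,,,6/12,6/9,48,male,rural
u003,no,6/36,6/60,,,6/6,6/9,61,female,urban
u004,no,6/60,6/18,,,6/9,6/12,55,male,rural
u005,no,6/18,6/24,,,6/12,6/9,72,female,urban
u006,no,6/24,6/36,,,6/6,6/9,34,male,rural
u007,no,6/36,6/60,,,6/9,6/12,48,female,urban
u008,no,6/60,6/18,,,6/12,6/9,61,male,rural
u009,no,6/18,6/24,,,6/6,6/9,55,female,urban
u010,no,6/24,6/36,,,6/9,6/12,72,male,rural
u011,no,6/36,6/60,,,6/12,6/9,34,female,urban
u012,no,6/60,6/18,,,6/6,6/9,48,male,rural
u013,no,6/18,6/24,,,6/9,6/12,61,female,urban
u014,no,6/24,6/36,,,6/12,6/9,55,male,rural
u015,no,6/36,6/60,,,6/6,6/9,72,female,urban
u016,no,6/60,6/18,,,6/9,6/12,34,male,rural
u017,no,6/18,6/24,,,6/12,6/9,48,female,urban
u018,no,6/24,6/36,,,6/6,6/9,61,male,rural
u019,no,6/36,6/60,,,6/9,6/12,55,female,urban
u020,no,6/60,6/18,,,6/12,6/9,72,male,rural
u021,no,6/18,6/24,,,6/6,6/9,34,female,urban
u022,no,6/24,6/36,,,6/9,6/12,48,male,rural
u023,no,6/36,6/60,,,6/12,6/9,61,female,urban
u024,no,6/60,6/18,,,6/6,6/9,55,male,rural
u025,no,6/18,6/24,,,6/9,6/12,72,female,urban
u026,no,6/24,6/36,,,6/12,6/9,34,male,rural
u027,no,6/36,6/60,,,6/6,6/9,48,female,urban
u028,no,6/60,6/18,,,6/9,6/12,61,male,rural
u029,no,6/18,6/24,,,6/12,6/9,55,female,urban
u030,no,6/24,6/36,,,6/6,6/9,72,male,rural
u031,no,6/36,6/60,,,6/9,6/12,34,female,urban
u032,no,6/60,6/18,,,6/12,6/9,48,male,rural
u033,no,6/18,6/24,,,6/6,6/9,61,female,urban
u034,no,6/24,6/36,,,6/9,6/12,55,male,rural
u035,no,6/36,6/60,,,6/12,6/9,72,female,urban
u036,no,6/60,6/18,,,6/6,6/9,34,male,rural
u037,no,6/18,6/24,,,6/9,6/12,48,female,urban
u038,no,6/24,6/36,,,6/12,6/9,61,male,rural
u039,no,6/36,6/60,,,6/6,6/9,55,female,urban
u040,no,6/60,6/18,,,6/9,6/12,72,male,rural
u041,no,6/18,6/24,,,6/12,6/9,34,female,urban
u042,no,6/24,6/36,,,6/6,6/9,48,male,rural
u043,no,6/36,6/60,,,6/9,6/12,61,female,urban
u044,no,6/60,6/18,,,6/12,6/9,55,male,rural
u045,no,6/18,6/24,,,6/6,6/9,72,female,urban
u046,no,6/24,6/36,,,6/9,6/12,34,male,rural
u047,no,6/36,6/60,,,6/12,6/9,48,female,urban
u048,no,6/60,6/18,,,6/6,6/9,61,male,rural
u049,no,6/18,6/24,,,6/9,6/12,55,female,urban
u050,no,6/24,6/36,,,6/12,6/9,72,male,rural
n001,yes,6/6,6/9,6/6,6/6,,,28,male,urban
n002,yes,6/9,6/6,6/6,6/6,,,41,female,rural
n003,yes,6/12,6/12,6/6,6/6,,,50,male,urban
n004,yes,6/6,6/9,6/6,6/6,,,28,female,rural
n005,yes,6/9,6/6,6/6,6/6,,,41,male,urban
n006,yes,6/12,6/12,6/6,6/6,,,50,female,rural
n007,yes,6/6,6/9,6/6,6/6,,,28,male,urban
n008,yes,6/9,6/6,6/6,6/6,,,41,female,rural
n009,yes,6/12,6/12,6/6,6/6,,,50,male,urban
n010,yes,6/6,6/9,6/6,6/6,,,28,female,rural
n011,yes,6/9,6/6,6/6,6/6,,,41,male,urban
n012,yes,6/12,6/12,6/6,6/6,,,50,female,rural
n013,yes,6/6,6/9,6/6,6/6,,,28,male,urban
n014,yes,6/9,6/6,6/6,6/6,,,41,female,rural
n015,yes,6/12,6/12,6/6,6/6,,,50,male,urban
n016,yes,6/6,6/9,6/6,6/6,,,28,female,rural
n017,yes,6/9,6/6,6/6,6/6,,,41,male,urban
n018,yes,6/12,6/12,6/6,6/6,,,50,female,rural
n019,yes,6/6,6/9,6/6,6/6,,,28,male,urban
n020,yes,6/9,6/6,6/6,6/6,,,41,female,rural
b001,yes,6/36,6/60,6/18,6/24,6/9,6/12,58,female,urban
b002,yes,6/60,6/36,6/24,6/18,6/9,6/12,66,male,rural
b003,yes,6/36,6/60,6/18,6/24,6/9,6/12,58,female,urban
b004,yes,6/60,6/36,6/24,6/18,6/9,6/12,66,male,rural
b005,yes,6/36,6/60,6/18,6/24,6/9,6/12,58,female,urban
a001,yes,6/18,6/24,6/6,6/9,,,45,male,rural
a002,yes,6/24,6/18,6/9,6/6,,,52,female,urban
a003,yes,6/36,6/60,6/12,6/12,,,38,male,rural
a004,yes,6/18,6/24,6/6,6/9,,,63,female,urban
a005,yes,6/24,6/18,6/9,6/6,,,45,male,rural
a006,yes,6/36,6/60,6/12,6/12,,,52,female,urban
a007,yes,6/18,6/24,6/6,6/9,,,38,male,rural
a008,yes,6/24,6/18,6/9,6/6,,,63,female,urban
a009,yes,6/36,6/60,6/12,6/12,,,45,male,rural
a010,yes,6/18,6/24,6/6,6/9,,,52,female,urban
a011,yes,6/24,6/18,6/9,6/6,,,38,male,rural
a012,yes,6/36,6/60,6/12,6/12,,,63,female,urban
a013,yes,6/18,6/24,6/6,6/9,,,45,male,rural
a014,yes,6/24,6/18,6/9,6/6,,,52,female,urban
a015,yes,6/36,6/60,6/12,6/12,,,38,male,rural
a016,yes,6/18,6/24,6/6,6/9,,,63,female,urban
a017,yes,6/24,6/18,6/9,6/6,,,45,male,rural
a018,yes,6/36,6/60,6/12,6/12,,,52,female,urban
a019,yes,6/18,6/24,6/6,6/9,,,38,male,rural
a020,yes,6/24,6/18,6/9,6/6,,,63,female,urban
a021,yes,6/36,6/60,6/12,6/12,,,45,male,rural
a022,yes,6/18,6/24,6/6,6/9,,,52,female,urban
a023,yes,6/24,6/18,6/9,6/6,,,38,male,rural
a024,yes,6/36,6/60,6/12,6/12,,,63,female,urban
a025,yes,6/18,6/24,6/6,6/9,,,45,male,rural
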