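curcumin
  invdock 3D (enol tautomer)

 47 48  0  0  0  0  0  0  0  0999 V2000
    1.3942    0.1055    1.8358 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6555    0.0240    1.1881 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.1364    1.1660    0.6010 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4777    2.4026    0.6015 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0339    3.5234   -0.0369 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3698    4.8405   -0.0313 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0387    5.0252   -0.0115 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4733    6.4038   -0.0092 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1707    7.4116   -0.0281 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0119    6.4862    0.0192 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6571    7.6671    0.0265 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0101    8.8864    0.0069 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1098    7.7509    0.0543 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8249    8.8897    0.0489 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.2979    8.9524    0.0765 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.9272   10.0483    0.6763 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.3230   10.1451    0.6995 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.1099    9.1494    0.1117 C   0  0  0  0  0  0  0  0  0  0  0  0
   -9.4693    9.2858    0.1593 O   0  0  0  0  0  0  0  0  0  0  0  0
   -7.5053    8.0527   -0.5086 C   0  0  0  0  0  0  0  0  0  0  0  0
   -8.0994    6.9895   -1.1344 O   0  0  0  0  0  0  0  0  0  0  0  0
   -9.5170    6.9479   -1.1873 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.1025    7.9754   -0.5263 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.2886    3.3944   -0.6484 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9600    2.1677   -0.6526 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.3802    1.0625   -0.0333 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.0325   -0.1420   -0.0357 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.1512   -0.8859    2.2290 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6046    0.3851    1.1301 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4317    0.7996    2.6821 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5289    2.5119    1.1126 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0365    5.7020   -0.0593 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3425    4.1968   -0.0074 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5631    5.5537    0.0331 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0424    8.7176   -0.0153 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6337    6.7994    0.0924 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3144    9.8515    0.0356 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.3374   10.8366    1.1403 H   0  0  0  0  0  0  0  0  0  0  0  0
   -7.7773   11.0057    1.1820 H   0  0  0  0  0  0  0  0  0  0  0  0
   -9.6924   10.1152    0.6117 H   0  0  0  0  0  0  0  0  0  0  0  0
   -9.7998    6.0254   -1.7044 H   0  0  0  0  0  0  0  0  0  0  0  0
   -9.9161    7.7821   -1.7725 H   0  0  0  0  0  0  0  0  0  0  0  0
   -9.9532    6.8999   -0.1846 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.6471    7.1315   -1.0374 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.7564    4.2479   -1.1351 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.9276    2.0941   -1.1398 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.8820   -0.0464   -0.4922 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 28  1  0  0  0  0
  1 29  1  0  0  0  0
  1 30  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  3 26  2  0  0  0  0
  4  5  2  0  0  0  0
  4 31  1  0  0  0  0
  5  6  1  0  0  0  0
  5 24  1  0  0  0  0
  6  7  2  0  0  0  0
  6 32  1  0  0  0  0
  7  8  1  0  0  0  0
  7 33  1  0  0  0  0
  8  9  2  0  0  0  0
  8 10  1  0  0  0  0
 10 11  2  0  0  0  0
 10 34  1  0  0  0  0
 11 12  1  0  0  0  0
 11 13  1  0  0  0  0
 12 35  1  0  0  0  0
 13 14  2  0  0  0  0
 13 36  1  0  0  0  0
 14 15  1  0  0  0  0
 14 37  1  0  0  0  0
 15 16  1  0  0  0  0
 15 23  2  0  0  0  0
 16 17  2  0  0  0  0
 16 38  1  0  0  0  0
 17 18  1  0  0  0  0
 17 39  1  0  0  0  0
 18 19  1  0  0  0  0
 18 20  2  0  0  0  0
 19 40  1  0  0  0  0
 20 21  1  0  0  0  0
 20 23  1  0  0  0  0
 21 22  1  0  0  0  0
 22 41  1  0  0  0  0
 22 42  1  0  0  0  0
 22 43  1  0  0  0  0
 23 44  1  0  0  0  0
 24 25  2  0  0  0  0
 24 45  1  0  0  0  0
 25 26  1  0  0  0  0
 25 46  1  0  0  0  0
 26 27  1  0  0  0  0
 27 47  1  0  0  0  0
M  END
$$$$
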