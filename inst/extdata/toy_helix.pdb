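ATOM      1  N   LEU A   1      -0.315  -0.964  -8.034  1.00  0.00              
ATOM      2  CA  LEU A   1       0.847  -1.272  -7.210  1.00  0.00              
ATOM      3  C   LEU A   1       0.987  -0.280  -6.060  1.00  0.00              
ATOM      4  O   LEU A   1       1.199  -0.671  -4.912  1.00  0.00              
ATOM      5  SCM LEU A   1       0.689  -3.695  -6.280  1.00  0.00              
ATOM      6  N   VAL A   2       0.867   1.005  -6.377  1.00  0.00              
ATOM      7  CA  VAL A   2       0.979   2.056  -5.372  1.00  0.00              
ATOM      8  C   VAL A   2      -0.034   1.856  -4.249  1.00  0.00              
ATOM      9  O   VAL A   2       0.308   1.940  -3.070  1.00  0.00              
ATOM     10  SCM VAL A   2       2.786   2.110  -4.639  1.00  0.00              
ATOM     11  N   SER A   3      -1.281   1.591  -4.625  1.00  0.00              
ATOM     12  CA  SER A   3      -2.345   1.378  -3.651  1.00  0.00              
ATOM     13  C   SER A   3      -1.999   0.243  -2.694  1.00  0.00              
ATOM     14  O   SER A   3      -2.147   0.375  -1.479  1.00  0.00              
ATOM     15  SCM SER A   3      -2.682   2.973  -2.675  1.00  0.00              
ATOM     16  N   GLU A   4      -1.536  -0.872  -3.249  1.00  0.00              
ATOM     17  CA  GLU A   4      -1.168  -2.032  -2.447  1.00  0.00              
ATOM     18  C   GLU A   4      -0.111  -1.671  -1.408  1.00  0.00              
ATOM     19  O   GLU A   4      -0.229  -2.030  -0.237  1.00  0.00              
ATOM     20  SCM GLU A   4      -3.666  -3.223  -1.049  1.00  0.00              
ATOM     21  N   LYS A   5       0.923  -0.960  -1.846  1.00  0.00              
ATOM     22  CA  LYS A   5       2.002  -0.549  -0.956  1.00  0.00              
ATOM     23  C   LYS A   5       1.469   0.261   0.220  1.00  0.00              
ATOM     24  O   LYS A   5       1.830   0.014   1.371  1.00  0.00              
ATOM     25  SCM LYS A   5       3.760  -3.342   0.209  1.00  0.00              
ATOM     26  N   THR A   6       0.607   1.229  -0.076  1.00  0.00              
ATOM     27  CA  THR A   6       0.023   2.076   0.956  1.00  0.00              
ATOM     28  C   THR A   6      -0.704   1.244   2.007  1.00  0.00              
ATOM     29  O   THR A   6      -0.528   1.452   3.208  1.00  0.00              
ATOM     30  SCM THR A   6       1.363   3.140   1.782  1.00  0.00              
ATOM     31  N   GLN A   7      -1.521   0.301   1.548  1.00  0.00              
ATOM     32  CA  GLN A   7      -2.275  -0.564   2.447  1.00  0.00              
ATOM     33  C   GLN A   7      -1.349  -1.311   3.400  1.00  0.00              
ATOM     34  O   GLN A   7      -1.593  -1.363   4.605  1.00  0.00              
ATOM     35  SCM GLN A   7      -4.348   1.087   4.056  1.00  0.00              
ATOM     36  N   ASN A   8      -0.285  -1.889   2.851  1.00  0.00              
ATOM     37  CA  ASN A   8       0.680  -2.634   3.651  1.00  0.00              
ATOM     38  C   ASN A   8       1.262  -1.766   4.762  1.00  0.00              
ATOM     39  O   ASN A   8       1.341  -2.188   5.916  1.00  0.00              
ATOM     40  SCM ASN A   8      -0.383  -4.675   4.627  1.00  0.00              
ATOM     41  N   ASP A   9       1.670  -0.553   4.406  1.00  0.00              
ATOM     42  CA  ASP A   9       2.246   0.376   5.372  1.00  0.00              
ATOM     43  C   ASP A   9       1.287   0.633   6.529  1.00  0.00              
ATOM     44  O   ASP A   9       1.680   0.591   7.695  1.00  0.00              
ATOM     45  SCM ASP A   9       4.420  -0.500   6.240  1.00  0.00              
ATOM     46  N   ARG A  10       0.027   0.900   6.199  1.00  0.00              
ATOM     47  CA  ARG A  10      -0.990   1.165   7.210  1.00  0.00              
ATOM     48  C   ARG A  10      -1.104   0.006   8.194  1.00  0.00              
ATOM     49  O   ARG A  10      -1.135   0.210   9.408  1.00  0.00              
ATOM     50  SCM ARG A  10      -0.148   4.637   9.220  1.00  0.00              
END   
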