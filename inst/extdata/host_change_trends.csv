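scenario,period,species,ISH,LSH,MSH,HSH
SSP126,2020-2040,A. splendens,-0.07,0.03,0.09,0.60
SSP126,2040-2060,A. splendens,-0.12,0.07,0.18,0.95
SSP126,2060-2080,A. splendens,-0.11,0.06,0.17,0.90
SSP126,2080-2100,A. splendens,-0.11,0.07,0.17,0.89
SSP245,2020-2040,A. splendens,-0.09,0.06,0.14,0.72
SSP245,2040-2060,A. splendens,-0.16,0.09,0.27,1.26
SSP245,2060-2080,A. splendens,-0.18,0.08,0.30,1.49
SSP245,2080-2100,A. splendens,-0.21,0.06,0.37,1.80
SSP370,2020-2040,A. splendens,-0.09,0.07,0.14,0.71
SSP370,2040-2060,A. splendens,-0.16,0.09,0.25,1.25
SSP370,2060-2080,A. splendens,-0.23,0.05,0.41,1.98
SSP370,2080-2100,A. splendens,-0.30,-0.01,0.53,2.88
SSP585,2020-2040,A. splendens,-0.11,0.07,0.17,0.85
SSP585,2040-2060,A. splendens,-0.18,0.08,0.29,1.49
SSP585,2060-2080,A. splendens,-0.26,0.00,0.48,2.44
SSP585,2080-2100,A. splendens,-0.39,0.10,0.45,3.82
SSP126,2020-2040,K. cuspidatum,-0.13,-0.02,0.17,0.31
SSP126,2040-2060,K. cuspidatum,-0.20,-0.03,0.24,0.46
SSP126,2060-2080,K. cuspidatum,-0.20,-0.01,0.24,0.43
SSP126,2080-2100,K. cuspidatum,-0.18,-0.02,0.22,0.41
SSP245,2020-2040,K. cuspidatum,-0.17,-0.02,0.21,0.37
SSP245,2040-2060,K. cuspidatum,-0.25,-0.03,0.28,0.61
SSP245,2060-2080,K. cuspidatum,-0.31,0.01,0.29,0.73
SSP245,2080-2100,K. cuspidatum,-0.36,0.03,0.28,0.85
SSP370,2020-2040,K. cuspidatum,-0.16,-0.03,0.21,0.36
SSP370,2040-2060,K. cuspidatum,-0.27,-0.02,0.29,0.62
SSP370,2060-2080,K. cuspidatum,-0.42,0.07,0.28,0.99
SSP370,2080-2100,K. cuspidatum,-0.62,0.24,0.23,1.45
SSP585,2020-2040,K. cuspidatum,-0.18,-0.04,0.22,0.42
SSP585,2040-2060,K. cuspidatum,-0.31,0.00,0.30,0.71
SSP585,2060-2080,K. cuspidatum,-0.52,0.17,0.25,1.22
SSP585,2080-2100,K. cuspidatum,-0.74,0.24,0.20,1.90
SSP126,2020-2040,K. ceratoides,0.09,-0.09,-0.06,-0.17
SSP126,2040-2060,K. ceratoides,0.04,-0.05,0.02,-0.10
SSP126,2060-2080,K. ceratoides,0.07,-0.07,-0.03,-0.18
SSP126,2080-2100,K. ceratoides,0.07,-0.06,-0.04,-0.18
SSP245,2020-2040,K. ceratoides,0.04,-0.04,0.00,-0.12
SSP245,2040-2060,K. ceratoides,-0.01,-0.01,0.07,-0.02
SSP245,2060-2080,K. ceratoides,0.01,-0.03,0.04,-0.05
SSP245,2080-2100,K. ceratoides,0.00,-0.02,0.04,-0.01
SSP370,2020-2040,K. ceratoides,0.05,-0.04,-0.01,-0.14
SSP370,2040-2060,K. ceratoides,0.03,-0.04,0.03,-0.09
SSP370,2060-2080,K. ceratoides,-0.01,-0.01,0.06,-0.01
SSP370,2080-2100,K. ceratoides,-0.05,-0.01,0.07,0.19
SSP585,2020-2040,K. ceratoides,0.04,-0.05,0.00,-0.13
SSP585,2040-2060,K. ceratoides,0.02,-0.03,0.01,-0.09
SSP585,2060-2080,K. ceratoides,-0.02,-0.02,0.03,0.10
SSP585,2080-2100,K. ceratoides,-0.07,-0.03,0.09,0.36
SSP126,2020-2040,N. sibirica,-0.06,-0.03,-0.05,0.35
SSP126,2040-2060,N. sibirica,-0.08,-0.03,-0.08,0.47
SSP126,2060-2080,N. sibirica,-0.08,-0.03,-0.08,0.46
SSP126,2080-2100,N. sibirica,-0.07,-0.03,-0.08,0.44
SSP245,2020-2040,N. sibirica,-0.07,-0.02,-0.06,0.40
SSP245,2040-2060,N. sibirica,-0.10,-0.03,-0.12,0.61
SSP245,2060-2080,N. sibirica,-0.11,-0.03,-0.15,0.72
SSP245,2080-2100,N. sibirica,-0.12,-0.04,-0.17,0.80
SSP370,2020-2040,N. sibirica,-0.07,-0.02,-0.06,0.40
SSP370,2040-2060,N. sibirica,-0.11,-0.03,-0.12,0.65
SSP370,2060-2080,N. sibirica,-0.14,-0.05,-0.19,0.91
SSP370,2080-2100,N. sibirica,-0.18,-0.06,-0.24,1.15
SSP585,2020-2040,N. sibirica,-0.07,-0.03,-0.08,0.45
SSP585,2040-2060,N. sibirica,-0.11,-0.04,-0.15,0.71
SSP585,2060-2080,N. sibirica,-0.16,-0.06,-0.22,1.04
SSP585,2080-2100,N. sibirica,-0.21,-0.07,-0.26,1.33
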