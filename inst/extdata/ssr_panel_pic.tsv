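primer	alleles	pic
TWSSR-1	2	0.28
TWSSR-4	2	0.21
TWSSR-8	3	0.76
TWSSR-9	3	0.62
TWSSR-10	5	0.67
TWSSR-11	2	0.53
TWSSR-12	4	0.49
TWSSR-13	2	0.14
TWSSR-14	3	0.34
TWSSR-15	3	0.60
TWSSR-16	4	0.50
TWSSR-19	3	0.67
TWSSR-20	4	0.72
TWSSR-24	1	0.14
TWSSR-31	2	0.58
TWSSR-34	2	0.59
TWSSR-47	3	0.48
TWSSR-48	2	0.50
TWSSR-57	2	0.48
TWSSR-59	3	0.57
TWSSR-61	3	0.85
TWSSR-62	4	0.69
TWSSR-66	3	0.52
TWSSR-68	3	0.79
TWSSR-72	2	0.46
TWSSR-74	4	0.77
TWSSR-76	1	0.65
TWSSR-81	1	0.36
TWSSR-82	3	0.69
TWSSR-86	3	0.54
TWSSR-87	3	0.46
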