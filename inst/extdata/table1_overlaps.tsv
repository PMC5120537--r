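id	2crdA	2jtbA	3gkyC	1e76A	3e4hA	1wo0A	2oqjL	2uz6K	3lo2B	2nlsA	1gm2A	1orlA	1bzbA	2kriB	1du9A	2f91B	1xu2R	1tckA	2kmoA	1mmcA
2crdA	0.73	0.64	0.42	0.25	0.67	0.39	0.50	0.31	0.67	0.42	0.31	0.41	0.53	0.34	0.69	0.39	0.39	0.33	0.39	0.58
2jtbA	0.64	0.76	0.39	0.27	0.73	0.42	0.58	0.39	0.48	0.47	0.33	0.24	0.42	0.47	0.70	0.70	0.50	0.27	0.45	0.70
3gkyC	0.42	0.39	0.85	0.52	0.34	0.38	0.48	0.67	0.40	0.36	0.38	0.41	0.50	0.32	0.46	0.33	0.39	0.57	0.32	0.33
1e76A	0.25	0.27	0.52	0.77	0.31	0.53	0.47	0.75	0.33	0.31	0.67	0.26	0.31	0.26	0.32	0.24	0.31	0.63	0.25	0.33
3e4hA	0.67	0.73	0.34	0.31	0.79	0.38	0.55	0.38	0.37	0.42	0.38	0.37	0.34	0.45	0.69	0.61	0.44	0.45	0.23	0.77
1wo0A	0.39	0.42	0.38	0.53	0.38	0.71	0.74	0.53	0.50	0.33	0.65	0.22	0.28	0.34	0.54	0.45	0.36	0.47	0.34	0.37
2oqjL	0.50	0.58	0.48	0.47	0.55	0.74	0.66	0.53	0.33	0.39	0.58	0.26	0.34	0.45	0.61	0.58	0.50	0.47	0.27	0.57
2uz6K	0.31	0.39	0.67	0.75	0.38	0.53	0.53	0.80	0.40	0.31	0.50	0.30	0.41	0.37	0.39	0.27	0.42	0.63	0.25	0.37
3lo2B	0.67	0.48	0.40	0.33	0.37	0.50	0.33	0.40	0.91	0.72	0.30	0.33	0.38	0.39	0.50	0.55	0.39	0.37	0.43	0.63
2nlsA	0.42	0.47	0.36	0.31	0.42	0.33	0.39	0.31	0.72	0.91	0.25	0.50	0.36	0.42	0.56	0.42	0.47	0.33	0.34	0.28
1gm2A	0.31	0.33	0.38	0.67	0.38	0.65	0.58	0.50	0.30	0.25	0.80	0.20	0.19	0.29	0.39	0.33	0.31	0.47	0.25	0.33
1orlA	0.41	0.24	0.41	0.26	0.37	0.22	0.26	0.30	0.33	0.50	0.20	0.98	0.41	0.35	0.30	0.30	0.28	0.22	0.30	0.30
1bzbA	0.53	0.42	0.50	0.31	0.34	0.28	0.34	0.41	0.38	0.36	0.19	0.41	0.64	0.29	0.53	0.45	0.25	0.31	0.36	0.38
2kriB	0.34	0.47	0.32	0.26	0.45	0.34	0.45	0.37	0.39	0.42	0.29	0.35	0.29	0.77	0.42	0.45	0.50	0.32	0.48	0.55
1du9A	0.69	0.70	0.46	0.32	0.69	0.54	0.61	0.39	0.50	0.56	0.39	0.30	0.53	0.42	0.73	0.64	0.44	0.36	0.32	0.60
2f91B	0.39	0.70	0.33	0.24	0.61	0.45	0.58	0.27	0.55	0.42	0.33	0.30	0.45	0.45	0.64	0.90	0.42	0.30	0.27	0.61
1xu2R	0.39	0.50	0.39	0.31	0.44	0.36	0.50	0.42	0.39	0.47	0.31	0.28	0.25	0.50	0.44	0.42	0.75	0.39	0.43	0.47
1tckA	0.33	0.27	0.57	0.63	0.45	0.47	0.47	0.63	0.37	0.33	0.47	0.22	0.31	0.32	0.36	0.30	0.39	0.79	0.30	0.47
2kmoA	0.39	0.45	0.32	0.25	0.23	0.34	0.27	0.25	0.43	0.34	0.25	0.30	0.36	0.48	0.32	0.27	0.43	0.30	0.77	0.36
1mmcA	0.58	0.70	0.33	0.33	0.77	0.37	0.57	0.37	0.63	0.28	0.33	0.30	0.38	0.55	0.60	0.61	0.47	0.47	0.36	0.79
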