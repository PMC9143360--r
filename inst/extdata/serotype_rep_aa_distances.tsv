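id	AAV1	AAV2	AAV3	AAV4	AAV6	AAV7	AAV8	AAV10	AAV11	AAV12	AAV13
AAV1	0	0.17	0.16	0.14	0.02	0.03	0.05	0.07	0.07	0.15	0.15
AAV2	0.17	0	0.18	0.19	0.18	0.16	0.18	0.17	0.16	0.19	0.18
AAV3	0.16	0.18	0	0.06	0.16	0.16	0.18	0.16	0.16	0.19	0.06
AAV4	0.14	0.19	0.06	0	0.15	0.15	0.16	0.16	0.15	0.17	0.02
AAV6	0.02	0.18	0.16	0.15	0	0.04	0.05	0.08	0.07	0.15	0.15
AAV7	0.03	0.16	0.16	0.15	0.04	0	0.03	0.07	0.06	0.14	0.15
AAV8	0.05	0.18	0.18	0.16	0.05	0.03	0	0.07	0.06	0.16	0.16
AAV10	0.07	0.17	0.16	0.16	0.08	0.07	0.07	0	0.02	0.16	0.16
AAV11	0.07	0.16	0.16	0.15	0.07	0.06	0.06	0.02	0	0.16	0.15
AAV12	0.15	0.19	0.19	0.17	0.15	0.14	0.16	0.16	0.16	0	0.18
AAV13	0.15	0.18	0.06	0.02	0.15	0.15	0.16	0.16	0.15	0.18	0
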