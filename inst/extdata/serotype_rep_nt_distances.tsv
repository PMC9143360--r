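id	AAV1	AAV2	AAV3	AAV4	AAV6	AAV7	AAV8	AAV10	AAV11	AAV12	AAV13
AAV1	0	0.16	0.12	0.11	0.02	0.03	0.04	0.05	0.05	0.12	0.12
AAV2	0.16	0	0.14	0.14	0.15	0.15	0.16	0.16	0.15	0.14	0.14
AAV3	0.12	0.14	0	0.05	0.13	0.12	0.13	0.12	0.12	0.13	0.05
AAV4	0.11	0.14	0.05	0	0.12	0.12	0.13	0.12	0.12	0.13	0.03
AAV6	0.02	0.15	0.13	0.12	0	0.05	0.06	0.07	0.06	0.13	0.13
AAV7	0.03	0.15	0.12	0.12	0.05	0	0.03	0.05	0.04	0.12	0.12
AAV8	0.04	0.16	0.13	0.13	0.06	0.03	0	0.05	0.05	0.13	0.14
AAV10	0.05	0.16	0.12	0.12	0.07	0.05	0.05	0	0.01	0.13	0.13
AAV11	0.05	0.15	0.12	0.12	0.06	0.04	0.05	0.01	0	0.12	0.13
AAV12	0.12	0.14	0.13	0.13	0.13	0.12	0.13	0.13	0.12	0	0.13
AAV13	0.12	0.14	0.05	0.03	0.13	0.12	0.14	0.13	0.13	0.13	0
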