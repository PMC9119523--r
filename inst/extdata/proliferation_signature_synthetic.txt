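MKI67
PCNA
TOP2A
CCNB1
CCNB2
CCNA2
BUB1
BUB1B
AURKA
AURKB
CDK1
CDC20
PLK1
FOXM1
TYMS
RRM2
MCM2
MCM3
MCM4
MCM5
MCM6
MCM7
E2F1
CDC6
CDC45
KIF11
PRLF-SYN-001
PRLF-SYN-002
PRLF-SYN-003
PRLF-SYN-004
PRLF-SYN-005
PRLF-SYN-006
PRLF-SYN-007
PRLF-SYN-008
PRLF-SYN-009
PRLF-SYN-010
PRLF-SYN-011
PRLF-SYN-012
PRLF-SYN-013
PRLF-SYN-014
PRLF-SYN-015
PRLF-SYN-016
PRLF-SYN-017
PRLF-SYN-018
PRLF-SYN-019
PRLF-SYN-020
PRLF-SYN-021
PRLF-SYN-022
PRLF-SYN-023
PRLF-SYN-024
PRLF-SYN-025
PRLF-SYN-026
PRLF-SYN-027
PRLF-SYN-028
PRLF-SYN-029
PRLF-SYN-030
PRLF-SYN-031
PRLF-SYN-032
PRLF-SYN-033
PRLF-SYN-034
PRLF-SYN-035
PRLF-SYN-036
PRLF-SYN-037
PRLF-SYN-038
PRLF-SYN-039
PRLF-SYN-040
PRLF-SYN-041
PRLF-SYN-042
PRLF-SYN-043
PRLF-SYN-044
PRLF-SYN-045
PRLF-SYN-046
PRLF-SYN-047
PRLF-SYN-048
PRLF-SYN-049
PRLF-SYN-050
PRLF-SYN-051
PRLF-SYN-052
PRLF-SYN-053
PRLF-SYN-054
PRLF-SYN-055
PRLF-SYN-056
PRLF-SYN-057
PRLF-SYN-058
PRLF-SYN-059
PRLF-SYN-060
PRLF-SYN-061
PRLF-SYN-062
PRLF-SYN-063
PRLF-SYN-064
PRLF-SYN-065
PRLF-SYN-066
PRLF-SYN-067
PRLF-SYN-068
PRLF-SYN-069
PRLF-SYN-070
PRLF-SYN-071
PRLF-SYN-072
PRLF-SYN-073
PRLF-SYN-074
PRLF-SYN-075
PRLF-SYN-076
PRLF-SYN-077
PRLF-SYN-078
PRLF-SYN-079
PRLF-SYN-080
PRLF-SYN-081
PRLF-SYN-082
PRLF-SYN-083
PRLF-SYN-084
PRLF-SYN-085
PRLF-SYN-086
PRLF-SYN-087
PRLF-SYN-088
PRLF-SYN-089
PRLF-SYN-090
PRLF-SYN-091
PRLF-SYN-092
PRLF-SYN-093
PRLF-SYN-094
PRLF-SYN-095
PRLF-SYN-096
PRLF-SYN-097
PRLF-SYN-098
PRLF-SYN-099
PRLF-SYN-100
PRLF-SYN-101
PRLF-SYN-102
PRLF-SYN-103
PRLF-SYN-104
PRLF-SYN-105
PRLF-SYN-106
PRLF-SYN-107
PRLF-SYN-108
PRLF-SYN-109
PRLF-SYN-110
PRLF-SYN-111
PRLF-SYN-112
PRLF-SYN-113
PRLF-SYN-114
PRLF-SYN-115
PRLF-SYN-116
PRLF-SYN-117
PRLF-SYN-118
PRLF-SYN-119
PRLF-SYN-120
PRLF-SYN-121
PRLF-SYN-122
PRLF-SYN-123
PRLF-SYN-124
PRLF-SYN-125
PRLF-SYN-126
PRLF-SYN-127
PRLF-SYN-128
PRLF-SYN-129
PRLF-SYN-130
PRLF-SYN-131
PRLF-SYN-132
PRLF-SYN-133
PRLF-SYN-134
PRLF-SYN-135
PRLF-SYN-136
PRLF-SYN-137
PRLF-SYN-138
PRLF-SYN-139
PRLF-SYN-140
PRLF-SYN-141
PRLF-SYN-142
PRLF-SYN-143
PRLF-SYN-144
PRLF-SYN-145
PRLF-SYN-146
PRLF-SYN-147
PRLF-SYN-148
PRLF-SYN-149
PRLF-SYN-150
PRLF-SYN-151
PRLF-SYN-152
PRLF-SYN-153
PRLF-SYN-154
PRLF-SYN-155
PRLF-SYN-156
PRLF-SYN-157
PRLF-SYN-158
PRLF-SYN-159
PRLF-SYN-160
PRLF-SYN-161
PRLF-SYN-162
PRLF-SYN-163
PRLF-SYN-164
PRLF-SYN-165
PRLF-SYN-166
PRLF-SYN-167
PRLF-SYN-168
PRLF-SYN-169
PRLF-SYN-170
PRLF-SYN-171
PRLF-SYN-172
PRLF-SYN-173
PRLF-SYN-174
PRLF-SYN-175
PRLF-SYN-176
PRLF-SYN-177
PRLF-SYN-178
PRLF-SYN-179
PRLF-SYN-180
PRLF-SYN-181
PRLF-SYN-182
PRLF-SYN-183
PRLF-SYN-184
PRLF-SYN-185
PRLF-SYN-186
PRLF-SYN-187
PRLF-SYN-188
PRLF-SYN-189
PRLF-SYN-190
PRLF-SYN-191
PRLF-SYN-192
PRLF-SYN-193
PRLF-SYN-194
PRLF-SYN-195
PRLF-SYN-196
PRLF-SYN-197
PRLF-SYN-198
PRLF-SYN-199
PRLF-SYN-200
PRLF-SYN-201
PRLF-SYN-202
PRLF-SYN-203
PRLF-SYN-204
PRLF-SYN-205
PRLF-SYN-206
PRLF-SYN-207
PRLF-SYN-208
PRLF-SYN-209
PRLF-SYN-210
PRLF-SYN-211
PRLF-SYN-212
PRLF-SYN-213
PRLF-SYN-214
PRLF-SYN-215
PRLF-SYN-216
PRLF-SYN-217
PRLF-SYN-218
PRLF-SYN-219
PRLF-SYN-220
PRLF-SYN-221
PRLF-SYN-222
PRLF-SYN-223
PRLF-SYN-224
PRLF-SYN-225
PRLF-SYN-226
PRLF-SYN-227
PRLF-SYN-228
PRLF-SYN-229
PRLF-SYN-230
PRLF-SYN-231
PRLF-SYN-232
PRLF-SYN-233
PRLF-SYN-234
PRLF-SYN-235
PRLF-SYN-236
PRLF-SYN-237
PRLF-SYN-238
PRLF-SYN-239
PRLF-SYN-240
PRLF-SYN-241
PRLF-SYN-242
PRLF-SYN-243
PRLF-SYN-244
PRLF-SYN-245
PRLF-SYN-246
PRLF-SYN-247
PRLF-SYN-248
PRLF-SYN-249
PRLF-SYN-250
PRLF-SYN-251
PRLF-SYN-252
PRLF-SYN-253
PRLF-SYN-254
PRLF-SYN-255
PRLF-SYN-256
PRLF-SYN-257
PRLF-SYN-258
PRLF-SYN-259
PRLF-SYN-260
PRLF-SYN-261
PRLF-SYN-262
PRLF-SYN-263
PRLF-SYN-264
PRLF-SYN-265
PRLF-SYN-266
PRLF-SYN-267
PRLF-SYN-268
PRLF-SYN-269
PRLF-SYN-270
PRLF-SYN-271
PRLF-SYN-272
PRLF-SYN-273
PRLF-SYN-274
PRLF-SYN-275
PRLF-SYN-276
PRLF-SYN-277
PRLF-SYN-278
PRLF-SYN-279
PRLF-SYN-280
PRLF-SYN-281
PRLF-SYN-282
PRLF-SYN-283
PRLF-SYN-284
PRLF-SYN-285
PRLF-SYN-286
PRLF-SYN-287
PRLF-SYN-288
PRLF-SYN-289
PRLF-SYN-290
PRLF-SYN-291
PRLF-SYN-292
PRLF-SYN-293
PRLF-SYN-294
PRLF-SYN-295
PRLF-SYN-296
PRLF-SYN-297
PRLF-SYN-298
PRLF-SYN-299
PRLF-SYN-300
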